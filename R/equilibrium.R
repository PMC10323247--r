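#' Equilibrium state of the cargo/importin/Ran competition system
#'
#' Container for the totals, dissociation constants and (after
#' [solve_competition()]) the equilibrium species concentrations of the
#' minimal mass-action model in which importins sequester a microtubule-binding
#' cargo (here the augmin complex) and Ran-GTP in turn sequesters importin
#' beta, releasing the cargo.
#'
#' The model contains two coupled 1:1 equilibria:
#' \deqn{cargo + importin \rightleftharpoons cargo\cdot importin \quad (K_{d,ci})}
#' \deqn{Ran + importin\beta \rightleftharpoons Ran\cdot importin\beta \quad (K_{d,ri})}
#' Importin alpha alone is inert (it is autoinhibited and does not bind the
#' cargo by itself); when both importin alpha and beta are supplied they act
#' as a preformed 1:1 heterodimer whose abundance is limited by importin
#' beta. Ran binding renders importin unavailable for the cargo.
#'
#' @param aug_total total cargo (augmin) concentration, nM
#' @param impA_total total importin alpha, nM (inert on its own)
#' @param impB_total total importin beta (or alpha/beta heterodimer), nM
#' @param ran_total total Ran-GTP (e.g. RanQ69L), nM
#' @param kd_aug_imp dissociation constant of the cargo-importin complex, nM
#' @param kd_ran_impB dissociation constant of the Ran-importin beta complex, nM
#'
#' @return An object of class `equilibrium_state` with fields `aug_total`,
#'   `impA_total`, `impB_total`, `ran_total`, `kd_aug_imp`, `kd_ran_impB`,
#'   and, once solved, `free_aug_fraction` and a named numeric `species`
#'   vector (`aug_free`, `imp_free`, `ran_free`, `aug_imp`, `ran_imp`).
#' @seealso [solve_competition()]
#' @export
equilibrium_state <- function(aug_total, impB_total = 0, ran_total = 0,
                              kd_aug_imp = 13.1, kd_ran_impB = 0.1,
                              impA_total = 0) {
  tot <- c(aug_total = aug_total, impA_total = impA_total,
           impB_total = impB_total, ran_total = ran_total)
  if (any(!is.finite(tot)) || any(tot < 0))
    stop("all total concentrations must be finite and >= 0")
  if (!is.finite(kd_aug_imp) || kd_aug_imp <= 0 ||
      !is.finite(kd_ran_impB) || kd_ran_impB <= 0)
    stop("dissociation constants must be finite and > 0")
  structure(list(aug_total = aug_total, impA_total = impA_total,
                 impB_total = impB_total, ran_total = ran_total,
                 kd_aug_imp = kd_aug_imp, kd_ran_impB = kd_ran_impB,
                 free_aug_fraction = NA_real_, species = NULL),
            class = "equilibrium_state")
}

#' Solve the importin/Ran competition equilibrium
#'
#' Computes equilibrium concentrations for the coupled two-reaction
#' mass-action system described in [equilibrium_state()]. Only importin beta
#' (alone, or paired 1:1 with importin alpha) inhibits the cargo, so the
#' effective inhibitor total is `impB_total`. Given free importin
#' concentration \eqn{I}, mass action fixes both complexes:
#' \deqn{[cargo\cdot imp] = A_{tot} \frac{I}{K_{d,ci} + I},\qquad
#'       [Ran\cdot imp] = R_{tot} \frac{I}{K_{d,ri} + I}}
#' and importin conservation
#' \eqn{I + [cargo\cdot imp] + [Ran\cdot imp] = I_{tot}} is a strictly
#' increasing function of \eqn{I}, so the root is found by bisection on
#' \eqn{[0, I_{tot}]}.
#'
#' @param state an `equilibrium_state` (or a list with the same fields)
#' @param tol absolute tolerance of the conservation residual, nM
#' @param max_iter maximum bisection iterations
#' @return the input `equilibrium_state` with `species` and
#'   `free_aug_fraction` filled in. `free_aug_fraction` is defined as 1 when
#'   `aug_total` is 0 (nothing to sequester).
#' @examples
#' st <- equilibrium_state(aug_total = 1, impB_total = 100, ran_total = 0)
#' solve_competition(st)$free_aug_fraction
#' @export
solve_competition <- function(state, tol = 1e-12, max_iter = 200L) {
  if (!inherits(state, "equilibrium_state"))
    state <- do.call(equilibrium_state, state)
  A <- state$aug_total; I_tot <- state$impB_total; R_tot <- state$ran_total
  K1 <- state$kd_aug_imp; K2 <- state$kd_ran_impB

  residual <- function(I) {
    I + A * I / (K1 + I) + R_tot * I / (K2 + I) - I_tot
  }
  if (I_tot <= 0) {
    I <- 0
  } else {
    lo <- 0; hi <- I_tot            # residual(0) = -I_tot < 0, residual(I_tot) >= 0
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      if (residual(mid) > 0) hi <- mid else lo <- mid
      if ((hi - lo) < tol) break
    }
    I <- (lo + hi) / 2
    if (abs(residual(I)) > 1e-6)
      stop(sprintf("competition solve did not converge: residual %.3e nM", residual(I)))
  }
  aug_imp <- A * I / (K1 + I)
  ran_imp <- R_tot * I / (K2 + I)
  aug_free <- A - aug_imp
  ran_free <- R_tot - ran_imp
  state$species <- c(aug_free = aug_free, imp_free = I, ran_free = ran_free,
                     aug_imp = aug_imp, ran_imp = ran_imp)
  state$free_aug_fraction <- if (A > 0) aug_free / A else 1
  state
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Importin/Ran competition equilibrium\n")
  cat(sprintf("  totals (nM): cargo %.3g, impA %.3g, impB %.3g, Ran %.3g\n",
              x$aug_total, x$impA_total, x$impB_total, x$ran_total))
  cat(sprintf("  Kd (nM): cargo-importin %.3g, Ran-importin %.3g\n",
              x$kd_aug_imp, x$kd_ran_impB))
  if (!is.null(x$species)) {
    cat(sprintf("  free cargo fraction: %.4f\n", x$free_aug_fraction))
    print(round(x$species, 4))
  } else cat("  (unsolved; call solve_competition())\n")
  invisible(x)
}

#' Microtubule-competent cargo fraction over an inhibitor titration
#'
#' Convenience wrapper running [solve_competition()] over a vector of importin
#' concentrations (optionally with Ran rescue), as used to generate synthetic
#' dose-response experiments.
#'
#' @param aug_total cargo concentration, nM
#' @param impB_totals vector of importin (beta or alpha/beta) totals, nM
#' @param ran_total Ran-GTP total applied to every point, nM
#' @param kd_aug_imp,kd_ran_impB dissociation constants, nM
#' @return data.frame with columns `impB_total`, `ran_total`, `free_aug_fraction`
#' @export
competition_titration <- function(aug_total, impB_totals, ran_total = 0,
                                  kd_aug_imp = 13.1, kd_ran_impB = 0.1) {
  frac <- vapply(impB_totals, function(i) {
    solve_competition(equilibrium_state(
      aug_total = aug_total, impB_total = i, ran_total = ran_total,
      kd_aug_imp = kd_aug_imp, kd_ran_impB = kd_ran_impB))$free_aug_fraction
  }, numeric(1))
  data.frame(impB_total = impB_totals, ran_total = ran_total,
             free_aug_fraction = frac)
}
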