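#' Rescale a survival curve to universal coordinates
#'
#' Applies the collapse transformation: the abscissa becomes
#' `theta = t / t_scale` and the ordinate `y = S * t_scale / mean_T`.
#' For compact transport `t_scale` is the global mean first-passage time
#' and the rescaled curves approach `Phi_nu(theta)`; for noncompact
#' transport `t_scale` is the global mean reaction time and the limit is
#' `exp(-theta)`.  An exponential curve rescaled by its own mean maps onto
#' `exp(-theta)` exactly.
#'
#' @param curve an `rxn_survival` tibble (columns `t`, `S`, `halfwidth`).
#' @param mean_T mean reaction time from the curve's start.
#' @param t_scale global time scale (`tau_G` or `T_G`).
#' @return tibble with columns `theta`, `y`, `halfwidth` (rescaled).
#' @export
rescale_survival <- function(curve, mean_T, t_scale) {
  stopifnot(mean_T > 0, t_scale > 0)
  tibble(theta = curve$t / t_scale,
         y = curve$S * t_scale / mean_T,
         halfwidth = curve$halfwidth * t_scale / mean_T)
}

#' Quantify the collapse of rescaled survival curves
#'
#' Interpolates every curve onto a common `theta` window and reports
#' pairwise and versus-theory sup-norm and L2 distances, both absolute and
#' relative to the sup of the reference on the window.
#'
#' @param curves named list of rescaled curves (tibbles with `theta`, `y`).
#' @param theory optional function of `theta` giving the theoretical limit
#'   curve (e.g. `function(th) phi_universal(th, nu)`).
#' @param window numeric length-2 vector: the `theta` comparison window.
#' @param n_points number of interpolation points.
#' @return tibble with columns `curve1`, `curve2` (or `"theory"`), `sup`,
#'   `l2`, `sup_rel`.
#' @export
collapse_report <- function(curves, theory = NULL, window = c(0.3, 3),
                            n_points = 200) {
  stopifnot(length(curves) >= 1)
  if (is.null(names(curves))) names(curves) <- paste0("curve", seq_along(curves))
  th <- seq(window[1], window[2], length.out = n_points)
  for (cv in curves) {
    if (min(cv$theta) > window[1] || max(cv$theta) < window[2]) {
      stop("curve does not span the comparison window")
    }
  }
  vals <- lapply(curves, function(cv) approx(cv$theta, cv$y, xout = th)$y)
  ref_scale <- if (!is.null(theory)) max(abs(theory(th))) else
    max(vapply(vals, function(v) max(abs(v)), numeric(1)))
  rows <- list()
  dist_row <- function(n1, n2, v1, v2) {
    d <- v1 - v2
    tibble(curve1 = n1, curve2 = n2, sup = max(abs(d)),
           l2 = sqrt(mean(d^2) * (window[2] - window[1])),
           sup_rel = max(abs(d)) / ref_scale)
  }
  nm <- names(curves)
  if (length(curves) >= 2) {
    for (i in seq_len(length(curves) - 1)) {
      for (j in (i + 1):length(curves)) {
        rows[[length(rows) + 1]] <- dist_row(nm[i], nm[j], vals[[i]], vals[[j]])
      }
    }
  }
  if (!is.null(theory)) {
    tv <- theory(th)
    for (i in seq_along(curves)) {
      rows[[length(rows) + 1]] <- dist_row(nm[i], "theory", vals[[i]], tv)
    }
  }
  do.call(rbind, rows)
}

#' Write/read the common survival-curve CSV schema
#'
#' Columns `t`, `S`, `ci_lo`, `ci_hi`; shared by the Monte Carlo and
#' spectral producers so collapse analyses are source-agnostic.
#'
#' @param curve an `rxn_survival` tibble.
#' @param path file path.
#' @export
write_survival_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve[, c("t", "S", "ci_lo", "ci_hi")]),
                   path, row.names = FALSE)
  invisible(curve)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path)
  new_rxn_survival(tibble(t = df$t, S = df$S, ci_lo = df$ci_lo,
                          ci_hi = df$ci_hi,
                          halfwidth = (df$ci_hi - df$ci_lo) / 2, n = NA),
                   source = "file")
}
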