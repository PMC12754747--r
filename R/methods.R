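# S3 methods for the fitted alignment model.

#' @export
print.pet_alignment <- function(x, ...) {
  cat("Maximum-likelihood PET detector alignment\n")
  cat(sprintf("  %d blocks, %d parameters (%s), %d events in %d bins\n",
              x$blueprint$ndet, 6L * nrow(x$params$translations),
              if (is.null(x$params$share_map)) "per block" else "tied groups",
              x$n_events, x$n_bins))
  cat(sprintf("  %d Adam iterations, final NLL %.6g, profiled scale %.4g\n",
              x$control$iterations, tail(x$loss_trace, 1), x$scale))
  cat(sprintf("  max |T| = %.3f mm, max |R| = %.3f deg\n",
              max(abs(x$translations)), max(abs(x$rotations))))
  invisible(x)
}

#' Extract fitted alignment parameters
#'
#' @param object a `pet_alignment` fit.
#' @param ... ignored.
#' @return Ndet x 6 matrix: translations (mm) then rotations (degrees).
#' @export
coef.pet_alignment <- function(object, ...) {
  out <- cbind(object$translations, object$rotations)
  colnames(out) <- c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz")
  out
}

#' Summarize a fitted alignment
#'
#' Reports per-axis parameter magnitudes and, when a reference geometry is
#' supplied, Procrustes-registered alignment errors against it.
#'
#' @param object a `pet_alignment`.
#' @param reference optional ground-truth `pet_blueprint`.
#' @param ... ignored.
#' @export
summary.pet_alignment <- function(object, reference = NULL, ...) {
  out <- list(fit = object,
              par_abs_mean = colMeans(abs(coef(object))),
              loss_head = mean(head(object$loss_trace, 20)),
              loss_tail = mean(tail(object$loss_trace, 20)))
  if (!is.null(reference))
    out$errors <- alignment_errors(object$geometry, reference,
                                   procrustes = TRUE)
  class(out) <- "summary.pet_alignment"
  out
}

#' @export
print.summary.pet_alignment <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean NLL first 20 iters %.6g -> last 20 iters %.6g\n",
              x$loss_head, x$loss_tail))
  cat("  mean |parameter| per axis:\n")
  print(signif(x$par_abs_mean, 4))
  if (!is.null(x$errors)) {
    cat("  Procrustes-registered errors vs reference:\n")
    cat(sprintf("    dT (mm):  %s\n",
                paste(sprintf("%.4f", x$errors$delta_T), collapse = "  ")))
    cat(sprintf("    dR (deg): %s\n",
                paste(sprintf("%.3f", x$errors$delta_R), collapse = "  ")))
  }
  invisible(x)
}

#' Plot the optimization loss trace
#'
#' @param x a `pet_alignment`.
#' @param ... passed to [plot()].
#' @export
plot.pet_alignment <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "iteration", ylab = "negative log-likelihood", ...)
  k <- 20
  if (length(x$loss_trace) > k) {
    sm <- stats::filter(x$loss_trace, rep(1 / k, k), sides = 1)
    lines(seq_along(sm), sm, col = "red")
    legend("topright", c("batch NLL", "moving mean"), lty = 1,
           col = c("black", "red"), bty = "n")
  }
  invisible(x)
}

#' Expected counts under the fitted alignment
#'
#' @param object a `pet_alignment`.
#' @param newdata data.frame with columns d1, cr1, d2, cr2 and (for TOF
#'   fits) t.
#' @param ... passed to [expected_count()].
#' @export
predict.pet_alignment <- function(object, newdata, ...) {
  expected_count(newdata$d1, newdata$cr1, newdata$d2, newdata$cr2,
                 t = if (is.null(newdata$t)) 1L else newdata$t,
                 geometry = object$geometry, lut = object$lut,
                 tof = object$tof, scale = object$scale, ...)
}

#' Simulate coincidences from the fitted geometry
#'
#' @param object a `pet_alignment`.
#' @param nsim number of events.
#' @param seed optional seed.
#' @param phantom phantom or activity grid to emit from.
#' @param ... passed to [simulate_events()].
#' @export
simulate.pet_alignment <- function(object, nsim = 1, seed = NULL,
                                   phantom, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_events(object$geometry, phantom, n_events = nsim,
                  tof = object$tof, ...)
}
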