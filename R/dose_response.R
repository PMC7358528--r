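# Hill concentration-response analysis: block prediction, nonlinear
# least-squares fitting of (IC50, h), selectivity factors, Table-style
# reporting.

#' Hill equation block prediction
#'
#' `y = 100 / (1 + (ic50 / conc)^h)`: percent of current blocked at toxin
#' concentration `conc`. Fixed asymptotes 0 and 100 (2-parameter model).
#'
#' @param conc concentration, nM (> 0, vectorized).
#' @param ic50 half-maximal inhibitory concentration, nM (> 0).
#' @param h Hill coefficient (> 0).
#' @return percent block in (0, 100).
#' @export
hill_response <- function(conc, ic50, h) {
  if (any(conc <= 0) || ic50 <= 0 || h <= 0) {
    stop("conc, ic50 and h must all be positive")
  }
  100 / (1 + (ic50 / conc)^h)
}

#' Fit the Hill equation to concentration-response data
#'
#' Unweighted nonlinear least squares of the 2-parameter Hill model on
#' pooled points (replicates are not averaged first). Initialization:
#' `ic50` at the geometric mean of tested concentrations, `h = 1`; bounds
#' `ic50 > 0`, `h` in \[0.1, 5\]. Standard errors are the Gauss-Newton
#' curvature estimates `sigma^2 (J'J)^-1` at the optimum. The optimizer is
#' `nls(algorithm = "port")` with a log-scale Nelder-Mead/BFGS fallback;
#' failure to converge is flagged, never silent.
#'
#' @param data data frame with columns `conc` (nM, > 0) and `response`
#'   (percent block). At least 3 distinct concentrations are required.
#' @return a `toxsel_hillfit`: list with `ic50`, `h`, `se_ic50`, `se_h`,
#'   `rss`, `converged`, `n`, and the initialization used.
#' @export
fit_hill <- function(data) {
  if (!all(c("conc", "response") %in% names(data))) {
    stop("data needs 'conc' and 'response' columns")
  }
  conc <- as.numeric(data$conc)
  y <- as.numeric(data$response)
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (any(!is.finite(y))) stop("responses must be finite")
  if (length(unique(conc)) < 3L) {
    stop("need at least 3 distinct concentrations")
  }
  start_ic50 <- exp(mean(log(conc)))
  start <- c(ic50 = start_ic50, h = 1)
  out <- list(ic50 = start_ic50, h = 1, se_ic50 = NA_real_, se_h = NA_real_,
              rss = sum((y - hill_response(conc, start_ic50, 1))^2),
              converged = FALSE, n = length(y), start = start,
              bounds = list(ic50 = c(0, Inf), h = c(0.1, 5)))
  class(out) <- "toxsel_hillfit"
  if (stats::sd(y) < 1e-10) {
    out$message <- "responses carry no information (all identical)"
    return(out)
  }
  df <- data.frame(conc = conc, y = y)
  fit <- tryCatch(
    stats::nls(y ~ 100 / (1 + (ic50 / conc)^h), data = df,
               start = as.list(start), algorithm = "port",
               lower = c(ic50 = 1e-9, h = 0.1), upper = c(ic50 = Inf, h = 5),
               control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    out$ic50 <- unname(est["ic50"])
    out$h <- unname(est["h"])
    out$converged <- fit$convInfo$isConv %||% TRUE
  }
  # polish (or rescue) on log scale; objective is smooth in log parameters
  obj <- function(p) {
    yy <- 100 / (1 + (exp(p[1L]) / conc)^exp(p[2L]))
    sum((y - yy)^2)
  }
  p0 <- log(c(max(out$ic50, 1e-9), min(max(out$h, 0.1), 5)))
  op <- stats::optim(p0, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-14))
  op <- stats::optim(op$par, obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14))
  if (op$value <= obj(p0) + 1e-12) {
    out$ic50 <- exp(op$par[1L])
    out$h <- min(max(exp(op$par[2L]), 0.1), 5)
    out$converged <- isTRUE(out$converged) || op$convergence == 0
  }
  out$rss <- obj(log(c(out$ic50, out$h)))
  se <- hill_se(conc, y, out$ic50, out$h)
  out$se_ic50 <- se[1L]
  out$se_h <- se[2L]
  if (!is.finite(out$se_ic50) || !is.finite(out$se_h)) {
    out$converged <- out$converged && length(y) > 2L
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gauss-Newton standard errors from a finite-difference Jacobian
hill_se <- function(conc, y, ic50, h) {
  pred <- function(p) 100 / (1 + (p[1L] / conc)^p[2L])
  p <- c(ic50, h)
  J <- matrix(NA_real_, length(conc), 2L)
  for (j in 1:2) {
    dp <- max(abs(p[j]), 1e-8) * 1e-6
    up <- p; up[j] <- up[j] + dp
    dn <- p; dn[j] <- dn[j] - dp
    J[, j] <- (pred(up) - pred(dn)) / (2 * dp)
  }
  dof <- length(y) - 2L
  if (dof <= 0L) return(c(NA_real_, NA_real_))
  sigma2 <- sum((y - pred(p))^2) / dof
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * sigma2, error = function(e)
    matrix(NA_real_, 2L, 2L))
  sqrt(pmax(diag(cov), 0))
}

#' @export
print.toxsel_hillfit <- function(x, ...) {
  cat(sprintf("<toxsel_hillfit> IC50 = %.3g +/- %.2g nM, h = %.3g +/- %.2g (n = %d, %s)\n",
              x$ic50, x$se_ic50, x$h, x$se_h, x$n,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Selectivity factor
#'
#' Ratio of IC50 (or Kd) values of one toxin on two channels,
#' `ic50_a / ic50_b`. Values below 1 favor channel A; e.g. a Kv1.1/Kv1.3
#' factor of 0.2 marks a Kv1.1-preferring toxin and 60 a Kv1.3-preferring
#' one.
#'
#' @param ic50_a,ic50_b positive IC50s (same units).
#' @return the ratio.
#' @export
selectivity_factor <- function(ic50_a, ic50_b) {
  if (any(ic50_a <= 0) || any(ic50_b <= 0)) stop("IC50s must be positive")
  ic50_a / ic50_b
}

#' Pairwise selectivity matrix
#'
#' @param ic50s named numeric vector of IC50s per channel.
#' @return matrix `m` with `m[a, b] = ic50[a] / ic50[b]`; antisymmetric
#'   under inversion (`m[a, b] * m[b, a] = 1`).
#' @export
selectivity_matrix <- function(ic50s) {
  if (is.null(names(ic50s))) stop("ic50s must be named by channel")
  outer(ic50s, ic50s, selectivity_factor)
}

#' Assemble an IC50 report table
#'
#' Long-to-wide assembly of per-toxin, per-channel Hill fits in the layout
#' of a pharmacology IC50 table: one row per toxin, one column per channel,
#' cells `IC50 +/- SE (h +/- SE)`; channels with no fit render `"N/A"`.
#'
#' @param fits data frame with columns `toxin`, `channel`, `ic50`,
#'   `ic50_se`, `h`, `h_se` (one row per successful fit), e.g. accumulated
#'   from [fit_hill()] results.
#' @param channels column order; default the channels present.
#' @return list with `table` (character matrix for display) and `long`
#'   (the numeric input, ordered), class `toxsel_ic50_table`.
#' @export
build_ic50_table <- function(fits, channels = NULL) {
  if (nrow(fits) == 0L) {
    return(structure(list(table = matrix(character(0), 0, 0), long = fits),
                     class = "toxsel_ic50_table"))
  }
  if (is.null(channels)) channels <- unique(fits$channel)
  toxins <- unique(fits$toxin)
  tab <- matrix("N/A", length(toxins), length(channels),
                dimnames = list(toxins, channels))
  for (i in seq_len(nrow(fits))) {
    if (!fits$channel[i] %in% channels) next
    tab[fits$toxin[i], fits$channel[i]] <-
      sprintf("%.1f ± %.1f (%.1f ± %.1f)", fits$ic50[i],
              fits$ic50_se[i], fits$h[i], fits$h_se[i])
  }
  long <- fits[order(match(fits$toxin, toxins), match(fits$channel, channels)), ]
  rownames(long) <- NULL
  structure(list(table = tab, long = long), class = "toxsel_ic50_table")
}

#' @export
print.toxsel_ic50_table <- function(x, ...) {
  print(x$table, quote = FALSE)
  invisible(x)
}

#' Write / read an IC50 table as CSV (numeric long format)
#' @param tab a `toxsel_ic50_table`.
#' @param path CSV file.
#' @export
write_ic50_table <- function(tab, path) {
  utils::write.csv(tab$long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ic50_table
#' @export
read_ic50_table <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  build_ic50_table(long)
}

#' Bundled published IC50 reference values
#'
#' The printed IC50 / Hill-coefficient reference set for the parent toxin
#' MeKTx13-3 (natural and recombinant) and its 4-substitution derivative
#' MeKTx13-3_AAAR on Kv1.1-1.6 (NA where a channel is insensitive). Units
#' nM; `h` dimensionless; SEs are standard errors of the mean.
#'
#' @return data frame with columns `toxin`, `channel`, `ic50`, `ic50_se`,
#'   `h`, `h_se`.
#' @export
ic50_reference <- function() {
  utils::read.csv(system.file("extdata", "ic50_reference.csv",
                              package = "toxsel", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
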