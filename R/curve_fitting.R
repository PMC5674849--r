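#' The constrained GR dose-response sigmoid
#'
#' Evaluates GR(c) = GRinf + (1 - GRinf) * GEC50^hGR / (GEC50^hGR + c^hGR).
#' By construction GR(0) = 1 (no drug, no effect) and GR(c) tends to GRinf
#' as c grows; GEC50 is the concentration of half-maximal effect, the
#' midpoint between 1 and GRinf; hGR is the Hill coefficient (steepness).
#'
#' @param c concentration(s), micromolar, >= 0.
#' @param grInf asymptotic GR value.
#' @param gec50 half-maximal-effect concentration, micromolar, > 0.
#' @param hGR Hill coefficient, > 0.
#' @return GR value(s) at `c`.
#' @examples
#' grSigmoid(0, -0.5, 1, 2)           # always 1 at zero dose
#' grSigmoid(1, 0.4, 1, 2)            # at c = GEC50: (1 + GRinf)/2 = 0.7
#' @export
grSigmoid <- function(c, grInf, gec50, hGR) {
  stopifnot(all(c >= 0), gec50 > 0, hGR > 0)
  # (c/gec50)^h form avoids overflow of gec50^h for extreme parameters
  grInf + (1 - grInf) / (1 + (c / gec50)^hGR)
}

#' Fitting options for the GR dose-response fit
#'
#' @param fTestAlpha significance level of the F-test comparing the sigmoid
#'   against a constant (flat) model; a fit that is not significantly better
#'   than flat is reported as `fit_class = "flat"`. Default 0.05.
#' @param flatTest set `FALSE` to disable the flat fallback and always
#'   report the sigmoid fit.
#' @param nRestarts number of additional randomly-jittered starts beyond
#'   the deterministic ones.
#' @param seed seed for the restart jitter (fixed for reproducibility).
#' @param factr,pgtol,maxit optimizer controls passed to
#'   [stats::optim()] (`L-BFGS-B`).
#' @return A list of class `grFitOptions`.
#' @export
grFitOptions <- function(fTestAlpha = 0.05, flatTest = TRUE, nRestarts = 4,
                         seed = 1L, factr = 1e2, pgtol = 1e-12,
                         maxit = 500L) {
  structure(list(fTestAlpha = fTestAlpha, flatTest = flatTest,
                 nRestarts = as.integer(nRestarts), seed = as.integer(seed),
                 factr = factr, pgtol = pgtol, maxit = as.integer(maxit)),
            class = "grFitOptions")
}

# sum of squared residuals in the (grInf, log10 gec50, hGR) parametrization
.grSSE <- function(conc, gr) {
  force(conc); force(gr)
  function(par) {
    pred <- grSigmoid(conc, par[1L], 10^par[2L], par[3L])
    sum((gr - pred)^2)
  }
}

#' Fit the constrained GR sigmoid to dose-response points
#'
#' Bounded least squares of the GR sigmoid against (concentration, GR)
#' points: GRinf in \[-1, 1\], hGR in \[0.1, 5\], and GEC50 (optimized in
#' log10 space, since tested doses span several orders of magnitude) within
#' two orders of magnitude of the tested concentration range. Multiple
#' deterministic starts (GEC50 at the geometric mean of the range and at
#' the concentration where GR crosses midway to its floor; hGR = 2; GRinf =
#' lowest observed GR) plus a few seeded jittered restarts guard against
#' the shallow local minima of low-Hill curves. Unless disabled, the fit is
#' compared with a constant model at the mean GR by an F-test; when the
#' sigmoid is not significantly better the fit is classed `"flat"` with
#' `grInf` equal to the mean GR.
#'
#' @param concentration tested concentrations, micromolar, all > 0; at
#'   least 4 distinct values.
#' @param gr GR values (typically replicate-averaged), same length.
#' @param options a [grFitOptions()] list.
#' @return A [GRFit] object.
#' @examples
#' conc <- 10 / 5^(8:0)
#' fit <- fitGRCurve(conc, grSigmoid(conc, 0.2, 0.5, 2))
#' fit
#' @export
fitGRCurve <- function(concentration, gr, options = grFitOptions()) {
  stopifnot(length(concentration) == length(gr))
  keep <- is.finite(concentration) & is.finite(gr)
  concentration <- concentration[keep]
  gr <- gr[keep]
  if (any(concentration <= 0))
    stop("fitGRCurve: all concentrations must be positive")
  n_distinct <- length(unique(concentration))
  if (n_distinct < 4L)
    stop("fitGRCurve: need at least 4 distinct concentrations to fit ",
         "3 parameters (got ", n_distinct, ")")
  n <- length(gr)
  c_min <- min(concentration)
  c_max <- max(concentration)

  gr_mean <- mean(gr)
  rss_flat <- sum((gr - gr_mean)^2)
  tss <- rss_flat
  if (tss < .Machine$double.eps * n) {
    # zero-variance input: no dose effect to fit, the constant IS the curve
    return(methods::new("GRFit", grInf = min(max(gr_mean, -1), 1),
                        gec50 = NA_real_, hGR = NA_real_, fitClass = "flat",
                        rSquared = NA_real_, pFlat = NA_real_, cMin = c_min,
                        cMax = c_max, nPoints = n, converged = TRUE))
  }

  lower <- c(-1, log10(c_min) - 2, 0.1)
  upper <- c(1, log10(c_max) + 2, 5)

  # deterministic starts
  gr_lo <- max(min(gr), -1)
  mid <- (1 + gr_lo) / 2
  c_cross <- concentration[which.min(abs(gr - mid))]
  lg_starts <- unique(c(mean(log10(c(c_min, c_max))), log10(c_cross),
                        log10(c_min), log10(c_max)))
  starts <- lapply(lg_starts, function(lg)
    c(min(max(gr_lo, -1), 1), lg, 2))
  # seeded jittered restarts
  if (options$nRestarts > 0L) {
    rng <- .seededRNG(options$seed)
    for (i in seq_len(options$nRestarts)) {
      starts[[length(starts) + 1L]] <- c(
        rng$runif1(-1, min(1, max(gr))),
        rng$runif1(lower[2L], upper[2L]),
        rng$runif1(0.5, 4))
    }
  }

  best <- NULL
  any_conv <- FALSE
  # small ndeps: the SSE surface is nearly flat in log10(GEC50) when the
  # curve midpoint sits near the edge of the tested range, and the default
  # finite-difference step stalls the optimizer short of the minimum
  ctrl <- list(factr = options$factr, pgtol = options$pgtol,
               maxit = options$maxit, ndeps = rep(1e-7, 3L))
  objective <- .grSSE(concentration, gr)
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      stats::optim(p0, objective, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }

  flatFit <- function(converged) {
    methods::new("GRFit", grInf = min(max(gr_mean, -1), 1), gec50 = NA_real_,
                 hGR = NA_real_, fitClass = "flat",
                 rSquared = if (tss > 0) 0 else NA_real_,
                 pFlat = NA_real_, cMin = c_min, cMax = c_max,
                 nPoints = n, converged = converged)
  }
  if (is.null(best) || !any_conv) {
    warning("fitGRCurve: optimizer failed to converge from all starts; ",
            "returning flat fit")
    return(flatFit(FALSE))
  }

  rss_sig <- best$value
  r2 <- if (tss > 0) 1 - rss_sig / tss else NA_real_
  p_flat <- NA_real_
  if (isTRUE(options$flatTest)) {
    # nested models: 1 parameter (constant) vs 3 (sigmoid)
    df1 <- 2L
    df2 <- n - 3L
    if (df2 < 1L) stop("fitGRCurve: not enough points for the F-test")
    if (rss_sig <= .Machine$double.eps * max(1, rss_flat)) {
      p_flat <- 0
    } else {
      f_stat <- ((rss_flat - rss_sig) / df1) / (rss_sig / df2)
      p_flat <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
    }
    if (!is.finite(p_flat) || p_flat >= options$fTestAlpha) {
      out <- flatFit(TRUE)
      out@pFlat <- p_flat
      return(out)
    }
  }
  methods::new("GRFit", grInf = best$par[1L], gec50 = 10^best$par[2L],
               hGR = best$par[3L], fitClass = "sigmoid", rSquared = r2,
               pFlat = p_flat, cMin = c_min, cMax = c_max, nPoints = n,
               converged = TRUE)
}

# small private RNG stream, isolated from the global .Random.seed
.seededRNG <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  env$runif1 <- function(lo, hi) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(1, lo, hi)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    x
  }
  env
}
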