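# Cycloheximide-chase turnover quantification: loading-control
# normalization, single-exponential decay fitting, half-life estimation,
# CHX/vehicle ratios, and the Mendelian cross-probability utility.

#' Construct a normalized decay series
#'
#' @param times hours, starting at 0, strictly increasing.
#' @param fractions remaining fraction at each time; re-normalized so the
#'   value at t = 0 is exactly 1.
#' @param protein,genotype optional condition labels.
#' @return object of class `"decay_series"`.
#' @export
decay_series <- function(times, fractions, protein = NA_character_,
                         genotype = NA_character_) {
  stopifnot(length(times) == length(fractions), length(times) >= 2)
  if (times[1] != 0) stop("series must start at t = 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(fractions <= 0)) stop("data error: non-positive fraction")
  fractions <- fractions / fractions[1]
  structure(list(times = as.numeric(times), fractions = fractions,
                 protein = protein, genotype = genotype),
            class = "decay_series")
}

#' @export
print.decay_series <- function(x, ...) {
  cat(sprintf("decay series%s: %s\n",
              if (is.na(x$protein)) "" else paste0(" (", x$protein,
                if (is.na(x$genotype)) "" else paste0("/", x$genotype), ")"),
              paste(sprintf("%.3g@%gh", x$fractions, x$times),
                    collapse = ", ")))
  invisible(x)
}

#' Normalize chase band intensities to a loading control
#'
#' `fraction(t) = (raw(t) / loading(t)) / (raw(0) / loading(0))`, so the
#' series is 1 at t = 0 by construction.
#'
#' @param raw_band band intensities of the protein of interest.
#' @param loading_band loading-control (e.g. tubulin) intensities, > 0.
#' @param times hours, must include t = 0 as the first point.
#' @param protein,genotype optional labels.
#' @return a [decay_series()].
#' @export
normalize_series <- function(raw_band, loading_band, times,
                             protein = NA_character_,
                             genotype = NA_character_) {
  stopifnot(length(raw_band) == length(loading_band),
            length(raw_band) == length(times))
  if (any(loading_band <= 0)) stop("data error: non-positive loading intensity")
  ord <- order(times)
  times <- times[ord]
  ratio <- (raw_band / loading_band)[ord]
  if (times[1] != 0) stop("data error: series must include a t = 0 point")
  decay_series(times, ratio / ratio[1], protein, genotype)
}

#' Fit a single-exponential decay and estimate the half-life
#'
#' Fits `f(t) = exp(-k t)` constrained through `(0, 1)`. The default method
#' is through-origin linear regression of `-ln(fraction)` on time (standard
#' for chase assays: `k = sum(t * y) / sum(t^2)`); `method = "nls"` refines
#' by nonlinear least squares on the linear scale. `half_life = ln(2) / k`;
#' a non-positive fitted rate is reported with `half_life = Inf` and
#' `nondecaying = TRUE`.
#'
#' @param series a [decay_series()] with >= 2 non-zero time points.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return object of class `"decay_fit"`: `rate_k` (per hour), `half_life`
#'   (hours), `rss` (residual sum of squares on the linear scale),
#'   `n_points`, `method`, `nondecaying`, plus the series labels.
#' @export
fit_decay <- function(series, method = c("loglinear", "nls")) {
  stopifnot(inherits(series, "decay_series"))
  method <- match.arg(method)
  t_nz <- series$times[series$times > 0]
  f_nz <- series$fractions[series$times > 0]
  if (length(t_nz) < 2) stop("need >= 2 non-zero time points")
  if (any(f_nz <= 0)) stop("data error: non-positive fraction")
  y <- -log(f_nz)
  k <- sum(t_nz * y) / sum(t_nz^2)
  if (method == "nls") {
    df <- data.frame(t = series$times, f = series$fractions)
    fit <- stats::nls(f ~ exp(-k * t), data = df,
                      start = list(k = max(k, 1e-6)),
                      control = stats::nls.control(maxiter = 200,
                                                   scaleOffset = 1))
    k <- unname(stats::coef(fit)["k"])
  }
  rss <- sum((series$fractions - exp(-k * series$times))^2)
  nondecaying <- k <= 0
  structure(list(rate_k = k,
                 half_life = if (nondecaying) Inf else log(2) / k,
                 rss = rss, n_points = length(series$times),
                 method = method, nondecaying = nondecaying,
                 protein = series$protein, genotype = series$genotype),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay fit (%s): k = %.5f /h, half-life = %.2f h, rss = %.4g\n",
              x$method, x$rate_k, x$half_life, x$rss))
  invisible(x)
}

#' CHX/vehicle band-intensity ratios
#'
#' Per protein: `(chx / loading_chx) / (vehicle / loading_vehicle)`. A value
#' of 0.40 reads as the drug-treated level being reduced to 40% of the
#' vehicle-treated level (a 60% decrease).
#'
#' @param chx,vehicle band intensities (matched lengths; names preserved).
#' @param loading_chx,loading_vehicle loading-control intensities, > 0.
#' @return numeric vector of ratios.
#' @export
chx_vehicle_ratio <- function(chx, vehicle, loading_chx, loading_vehicle) {
  n <- length(chx)
  stopifnot(length(vehicle) == n, length(loading_chx) == n,
            length(loading_vehicle) == n)
  if (any(loading_chx <= 0) || any(loading_vehicle <= 0))
    stop("data error: non-positive loading intensity")
  (chx / loading_chx) / (vehicle / loading_vehicle)
}

#' Expected offspring percentage for independent loci
#'
#' Product of per-locus transmission probabilities times 100. A cross
#' requiring a mutant allele (1/2), a floxed allele (1/2) and a Cre
#' transgene (1/2) gives 12.5%.
#'
#' @param loci numeric vector of per-locus probabilities, each in `[0, 1]`.
#' @return expected percentage of offspring.
#' @export
cross_probability <- function(loci) {
  if (length(loci) == 0) stop("at least one locus required")
  if (any(!is.finite(loci)) || any(loci < 0 | loci > 1))
    stop("locus probability outside [0, 1]")
  100 * prod(loci)
}
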