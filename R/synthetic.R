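#' Shape parameters of a synthetic vesicle-fusion transient
#'
#' A single fusion event recorded amperometrically shows a low baseline, a
#' fast rise to a peak of some tens of pA and a roughly exponential decay.
#' `fusion_params()` fixes one parametric template; patterns generated from
#' it differ by additive Gaussian noise, emulating repeated recordings of
#' the same release site.  `draw_fusion_params()` samples one template from
#' the documented default ranges (peak 30-70 pA, baseline 2-8 pA, rise
#' fraction 0.2-0.35, decay constant N/4-N/2 samples, noise SD 1-3 pA),
#' which is how each benchmark set obtains its conditions.
#'
#' @param n_samples Pattern length `N`.
#' @param peak_amplitude Peak current in pA.
#' @param baseline Baseline current in pA.
#' @param rise_fraction Fraction of the window before the peak.
#' @param decay_tau Exponential decay constant in samples.
#' @param noise_sd Additive Gaussian noise SD in pA.
#' @return A list of class `fusion_params`.
#' @export
fusion_params <- function(n_samples, peak_amplitude = 50, baseline = 5,
                          rise_fraction = 0.275, decay_tau = 0.375 * n_samples,
                          noise_sd = 2) {
  stopifnot(n_samples >= 2, n_samples == round(n_samples))
  stopifnot(peak_amplitude >= 0, baseline >= 0,
            rise_fraction > 0, rise_fraction < 1,
            decay_tau > 0, noise_sd >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 peak_amplitude = peak_amplitude, baseline = baseline,
                 rise_fraction = rise_fraction, decay_tau = decay_tau,
                 noise_sd = noise_sd),
            class = "fusion_params")
}

#' @rdname fusion_params
#' @export
draw_fusion_params <- function(n_samples) {
  fusion_params(n_samples,
                peak_amplitude = stats::runif(1, 30, 70),
                baseline = stats::runif(1, 2, 8),
                rise_fraction = stats::runif(1, 0.2, 0.35),
                decay_tau = stats::runif(1, n_samples / 4, n_samples / 2),
                noise_sd = stats::runif(1, 1, 3))
}

# Noiseless fusion template: cubic rise to the peak, exponential decay.
fusion_template <- function(p) {
  n <- p$n_samples
  pk <- max(2L, round(p$rise_fraction * n))
  t <- seq_len(n)
  ifelse(t <= pk,
         p$baseline + (p$peak_amplitude - p$baseline) * (t / pk)^3,
         p$baseline + (p$peak_amplitude - p$baseline) *
           exp(-(t - pk) / p$decay_tau))
}

# All synthetic samples are clipped into the amperometric operating range.
clip_pa <- function(x) pmin(pmax(x, 0), 100)

#' The negative (non-fusion) waveform styles
#'
#' @return Character vector of the five style names.
#' @export
negative_styles <- function() {
  c("flat_noise", "slow_drift", "double_bump", "truncated_rise", "late_peak")
}

# One negative pattern of the given style, amplitudes matched to the
# positive class so that discriminability comes from shape, not scale.
# late_peak is deliberately a hard negative: a full fusion-like transient
# whose peak falls mid-window instead of at the fusion rise fraction.
negative_pattern <- function(style, n, noise_sd) {
  t <- seq_len(n)
  sd <- noise_sd
  base <- stats::runif(1, 2, 8)
  x <- switch(style,
    flat_noise = rep(base, n),
    slow_drift = seq(base, stats::runif(1, 10, 30), length.out = n),
    double_bump = {
      a1 <- stats::runif(1, 40, 70); a2 <- stats::runif(1, 40, 70)
      w <- stats::runif(2, 0.5, 0.9)
      p1 <- (0.25 + stats::runif(1, -0.05, 0.05)) * n
      p2 <- (0.70 + stats::runif(1, -0.05, 0.05)) * n
      base + (a1 - base) * exp(-(t - p1)^2 / (2 * w[1]^2)) +
             (a2 - base) * exp(-(t - p2)^2 / (2 * w[2]^2))
    },
    truncated_rise = {
      pk <- stats::runif(1, 10, 30)
      p <- round(stats::runif(1, 0.2, 0.35) * n)
      tau <- stats::runif(1, 1, 3)
      ifelse(t <= p, base + (pk - base) * (t / p)^3,
             base + (pk - base) * exp(-(t - p) / tau))
    },
    late_peak = {
      pk <- stats::runif(1, 30, 70)
      p <- round(stats::runif(1, 0.45, 0.70) * n)
      tau <- stats::runif(1, n / 4, n / 2)
      ifelse(t <= p, base + (pk - base) * (t / p)^3,
             base + (pk - base) * exp(-(t - p) / tau))
    },
    stop("unknown negative style: ", style))
  clip_pa(x + stats::rnorm(n, 0, sd))
}

#' Labelled pattern collection
#'
#' @param patterns Numeric matrix, one pattern per row (pA).
#' @param labels Logical vector, `TRUE` = positive (fusion).
#' @param styles Optional per-row style annotation for negatives.
#' @param params Optional [fusion_params()] used for the positives.
#' @param seed Optional generating seed (recorded for the manifest).
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(patterns, labels, styles = NULL, params = NULL,
                        seed = NULL) {
  stopifnot(is.matrix(patterns), is.numeric(patterns))
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(patterns))
  structure(list(patterns = patterns, labels = labels, styles = styles,
                 params = params, seed = seed),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("Pattern set: %d patterns of length %d (%d positive, %d negative)\n",
              nrow(x$patterns), ncol(x$patterns), sum(x$labels),
              sum(!x$labels)))
  invisible(x)
}

#' Generate positive (fusion) patterns
#'
#' Each pattern is the noiseless template of `params` plus i.i.d. Gaussian
#' noise, clipped into the 0-100 pA amperometric range.  Deterministic
#' given the R random-number state.
#'
#' @param params A [fusion_params()] object.
#' @param count Number of patterns (>= 1).
#' @return A [pattern_set()] with all labels positive.
#' @export
make_positive <- function(params, count) {
  stopifnot(inherits(params, "fusion_params"), count >= 1)
  tmpl <- fusion_template(params)
  m <- t(vapply(seq_len(count), function(i)
    clip_pa(tmpl + stats::rnorm(params$n_samples, 0, params$noise_sd)),
    numeric(params$n_samples)))
  pattern_set(m, rep(TRUE, count), params = params)
}

#' Generate negative (non-fusion) patterns
#'
#' Draws a style per pattern from `styles` and synthesizes a waveform in
#' the same amplitude range as the positives: flat baseline noise, slow
#' electrode drift, two narrow transients, an aborted (truncated) rise
#' collapsing back to baseline, or a full transient peaking too late in
#' the window.
#'
#' @param params A [fusion_params()] object (supplies `n_samples`).
#' @param count Number of patterns.
#' @param styles Styles to draw from (default all of [negative_styles()]).
#' @return A [pattern_set()] with all labels negative and a `styles` field.
#' @export
make_negative <- function(params, count, styles = negative_styles()) {
  stopifnot(inherits(params, "fusion_params"), count >= 1)
  styles <- match.arg(styles, negative_styles(), several.ok = TRUE)
  if (length(styles) < 1L) stop("'styles' must name at least one style")
  drawn <- sample(styles, count, replace = TRUE)
  m <- t(vapply(drawn, function(s)
    negative_pattern(s, params$n_samples, params$noise_sd),
    numeric(params$n_samples)))
  rownames(m) <- NULL
  pattern_set(m, rep(FALSE, count), styles = drawn, params = params)
}

#' Generate the standard labelled benchmark
#'
#' Mirrors the experimental design used throughout the package: 40 positive
#' and 40 negative patterns at a given sampling `n_samples`.  One fusion
#' template is drawn per set from the documented ranges, the patterns are
#' generated, and rows are shuffled.  Fully deterministic given `seed`.
#'
#' @param n_samples Pattern length; the supported sweep is 10, 15, ..., 40.
#' @param n_pos,n_neg Class sizes (default 40 each).
#' @param seed Integer seed.
#' @param styles Negative styles to use.
#' @return A [pattern_set()].
#' @examples
#' bench <- make_benchmark(20, seed = 1)
#' table(bench$labels)
#' @export
make_benchmark <- function(n_samples, n_pos = 40, n_neg = 40, seed = 1,
                           styles = negative_styles()) {
  stopifnot(n_samples >= 2, n_pos >= 1, n_neg >= 1)
  set.seed(seed)
  params <- draw_fusion_params(n_samples)
  pos <- make_positive(params, n_pos)
  neg <- make_negative(params, n_neg, styles)
  m <- rbind(pos$patterns, neg$patterns)
  lab <- c(pos$labels, neg$labels)
  sty <- c(rep(NA_character_, n_pos), neg$styles)
  ord <- sample(nrow(m))
  pattern_set(m[ord, , drop = FALSE], lab[ord], styles = sty[ord],
              params = params, seed = seed)
}

#' Write / read a pattern set as delimited text
#'
#' One pattern per row, comma-separated, final integer column is the label
#' (1 = positive).  A JSON manifest with the seed and template parameters
#' is written alongside when available.
#'
#' @param x A [pattern_set()].
#' @param path CSV file path.
#' @param manifest Write `<path>.manifest.json` (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_patterns <- function(x, path, manifest = TRUE) {
  stopifnot(inherits(x, "pattern_set"))
  df <- cbind(as.data.frame(x$patterns), label = as.integer(x$labels))
  colnames(df) <- c(paste0("s", seq_len(ncol(x$patterns))), "label")
  utils::write.csv(df, path, row.names = FALSE)
  if (manifest) {
    man <- list(n_patterns = nrow(x$patterns), n_samples = ncol(x$patterns),
                n_positive = sum(x$labels), seed = x$seed,
                params = if (!is.null(x$params)) unclass(x$params),
                styles = x$styles)
    jsonlite::write_json(man, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  has_label <- colnames(df)[ncol(df)] == "label"
  if (has_label) {
    labels <- as.logical(df[[ncol(df)]])
    m <- as.matrix(df[, -ncol(df), drop = FALSE])
  } else {
    labels <- rep(NA, nrow(df))
    m <- as.matrix(df)
  }
  dimnames(m) <- NULL
  pattern_set(m, labels)
}
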