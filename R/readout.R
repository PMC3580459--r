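## Working-memory span readout, the condition runner linking pathology and
## pharmacology to the network, correlation against the clinical table,
## and the DOE screening / response-surface / sensitivity machinery.

#' Working-memory span of a spike raster
#'
#' Divides the time axis into bins of \code{bin_ms}, counts the distinct
#' stimulated neurons firing in each bin, and finds the bins where this
#' count strictly exceeds \code{M/2} (\code{M} = size of the stimulated
#' population).  The span is the time from the start of the first
#' qualifying bin to the end of the last, in seconds; no qualifying bin
#' (or an empty raster) gives 0.  Spikes from non-stimulated neurons and
#' the row order of the raster are irrelevant.
#'
#' @param sim An \code{adwm_sim_result}, or a raster data frame with
#'   columns \code{time_ms}, \code{neuron}.
#' @param stimulated_ids Ids of the stimulated population (defaults to the
#'   simulation's).
#' @param M Population size used for the threshold; defaults to
#'   \code{length(stimulated_ids)}.
#' @param bin_ms Bin width in ms (default 200).
#' @param threshold_frac Optional alternative rule: a bin qualifies when
#'   the count reaches at least this fraction of \code{M} (e.g. 0.8)
#'   instead of the strict \code{> M/2} rule.
#' @return Span in seconds.
#' @export
working_memory_span <- function(sim, stimulated_ids = NULL, M = NULL,
                                bin_ms = 200, threshold_frac = NULL) {
  if (inherits(sim, "adwm_sim_result")) {
    raster <- sim$raster
    if (is.null(stimulated_ids)) stimulated_ids <- sim$stimulated
    dur_ms <- sim$duration_s * 1000
  } else {
    raster <- sim
    if (is.null(stimulated_ids)) stop("`stimulated_ids` required for a bare raster")
    dur_ms <- if (nrow(raster)) max(raster$time_ms) else 0
  }
  if (bin_ms <= 0) stop("`bin_ms` must be positive")
  if (is.null(M)) M <- length(stimulated_ids)
  if (M < 1 || nrow(raster) == 0) return(0)
  r <- raster[raster$neuron %in% stimulated_ids, ]
  if (nrow(r) == 0) return(0)
  bin <- floor(r$time_ms / bin_ms)
  counts <- tapply(r$neuron, bin, function(n) length(unique(n)))
  qual <- if (is.null(threshold_frac)) counts > M / 2 else
    counts >= threshold_frac * M
  if (!any(qual)) return(0)
  bins <- as.numeric(names(counts))[qual]
  ((max(bins) + 1) * bin_ms - min(bins) * bin_ms) / 1000
}

## Cholinergic synapse used by the condition pipeline: same preset, shorter
## protocol (periodic steady state is reached well before the averaging
## window).  Cached per session together with its healthy control means.
.adwm_cache <- new.env(parent = emptyenv())

.pipeline_chol_cfg <- function() {
  if (is.null(.adwm_cache$chol_cfg))
    .adwm_cache$chol_cfg <- make_cholinergic_synapse(dt_ms = 0.02,
                                                     transient_s = 3,
                                                     averaging_s = 5)
  .adwm_cache$chol_cfg
}

.chol_activations <- function(quantal_scale = 1, halflife_ms = NULL) {
  key <- sprintf("chol_%.8g_%.8g", quantal_scale,
                 if (is.null(halflife_ms)) -1 else halflife_ms)
  if (is.null(.adwm_cache[[key]])) {
    tr <- simulate_synapse(.pipeline_chol_cfg(), quantal_scale = quantal_scale,
                           halflife_ms = halflife_ms, record_every_ms = 50)
    .adwm_cache[[key]] <- vapply(c(M1 = "M1", M2 = "M2", a7 = "a7", a4b2 = "a4b2"),
                                 function(p) tr$mean_activation[[p]][["ACh"]],
                                 numeric(1))
  }
  .adwm_cache[[key]]
}

#' Receptor activations for a trial condition
#'
#' Runs the cholinergic receptor-competition synapse for the condition's
#' ACh state (deficit/compensation scaling of release, AChE-I half-life
#' extension) against the healthy control, applies the SB-742457 5-HT6
#' activation presets and cascade, and the dopaminergic placebo tone.
#'
#' @param condition An \code{adwm_condition}.
#' @param P Coupling parameters (for the 5-HT6 cascade gain).
#' @return An \code{\link{receptor_activations}} set.
#' @export
condition_activations <- function(condition, P = coupling_params()) {
  stopifnot(inherits(condition, "adwm_condition"))
  st <- condition$state
  iv <- condition$intervention
  ctl <- .chol_activations()
  qs <- (1 - st$ach_deficit) * (1 + st$ach_compensation)
  hl <- NULL
  if (iv$mechanism == "AChE-I" && iv$dose_mg > 0)
    hl <- ache_dose_chain(iv$drug, iv$dose_mg)$halflife_ms
  trt <- .chol_activations(quantal_scale = qs, halflife_ms = hl)
  act <- receptor_activations(
    control = c(ctl, "5HT6" = unname(sb742457_activation()["0"])),
    treated = trt)
  if (iv$mechanism == "5HT6-antagonist") {
    lv <- sb742457_activation()
    key <- as.character(iv$dose_mg)
    if (!key %in% names(lv))
      stop("no 5-HT6 activation preset for dose ", iv$dose_mg, " mg")
    act$treated["5HT6"] <- lv[[key]]
    act <- apply_5ht6_cascade(act, P$P_5HT6)
  }
  if (st$da_placebo > 0)
    act$treated["D1"] <- min(1, act$treated["D1"] * (1 + st$da_placebo))
  act
}

#' Run a trial condition
#'
#' Full pipeline for one condition: build the network, apply the lesion of
#' the pathology state, the memantine transform if any, and the receptor
#' couplings; then run \code{n_trials} simulations with seeds
#' \code{base_seed + 1 .. base_seed + n_trials} (each trial redraws the
#' lesion and the background noise) and return the working-memory spans.
#'
#' @param condition An \code{adwm_condition} (or \code{NULL} for the
#'   healthy, lesion-free network).
#' @param n_trials Number of trials, at least 1.
#' @param base_seed Base integer seed.
#' @param net_cfg Network configuration.
#' @param P Coupling parameters.
#' @param duration_s Simulated seconds per trial.
#' @return Object of class \code{adwm_span_result}: \code{id},
#'   \code{spans}, \code{mean_span}, \code{sd_span} (\code{NA} for a
#'   single trial), \code{n_trials}, \code{base_seed}.
#' @export
run_condition <- function(condition = NULL, n_trials = 10, base_seed = 1L,
                          net_cfg = network_config(), P = coupling_params(),
                          duration_s = 15) {
  if (n_trials < 1) stop("`n_trials` must be at least 1")
  base_net <- build_network(seed = base_seed, cfg = net_cfg)
  if (!is.null(condition)) {
    stopifnot(inherits(condition, "adwm_condition"))
    act <- condition_activations(condition, P)
    iv <- condition$intervention
  }
  spans <- vapply(seq_len(n_trials), function(k) {
    seed_k <- base_seed + k
    net <- base_net
    if (!is.null(condition)) {
      net <- apply_lesion(net, condition$state, seed = seed_k)
      if (iv$mechanism == "memantine")
        net <- apply_memantine(net, iv$memantine_ee, iv$memantine_ei)
      net <- apply_couplings(net, act, P)
    }
    sim <- tryCatch(run_simulation(net, duration_s = duration_s, seed = seed_k),
                    error = function(e)
                      stop("condition ", if (is.null(condition)) "healthy" else
                           condition$id, ", seed ", seed_k, ": ",
                           conditionMessage(e), call. = FALSE))
    working_memory_span(sim)
  }, numeric(1))
  structure(list(id = if (is.null(condition)) "healthy" else condition$id,
                 spans = spans, mean_span = mean(spans),
                 sd_span = if (n_trials > 1) stats::sd(spans) else NA_real_,
                 n_trials = n_trials, base_seed = as.integer(base_seed)),
            class = "adwm_span_result")
}

#' @export
print.adwm_span_result <- function(x, ...) {
  cat(sprintf("<span result> %s: mean %.2f s (sd %s, n = %d)\n", x$id,
              x$mean_span,
              if (is.na(x$sd_span)) "NA [single trial]" else
                sprintf("%.2f", x$sd_span), x$n_trials))
  invisible(x)
}

#' The clinical ADAS-Cog calibration table
#'
#' The 28 therapeutic interventions (four drugs at up to three doses plus
#' placebo, at 12/26/52/78 weeks) with their reported ADAS-Cog effects
#' (points; positive = worse cognition), shipped as a CSV fixture.
#'
#' @param file Path to an alternative CSV with columns \code{drug},
#'   \code{dose_mg}, \code{weeks}, \code{adascog_effect}.
#' @return Data frame with 28 rows.
#' @export
clinical_table <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "adascog_clinical.csv", package = "adwm",
                        mustWork = TRUE)
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Correlate model spans with clinical outcomes
#'
#' Least-squares fit of the ADAS-Cog effects against the per-condition mean
#' working-memory spans (a polynomial of the requested degree).  Returns
#' the global slope, r-squared and F-test p-value, plus per-week sub-fits
#' for the 12, 26 and 52 week time points.  Since the ADAS-Cog effects are
#' changes from the trial baseline, an overall shift of the span axis only
#' moves the intercept; slope and r-squared are invariant, so absolute
#' spans and baseline-referenced span changes give identical fits.
#'
#' @param spans List of \code{adwm_span_result} (or numeric vector of mean
#'   spans), one per clinical record, in table order.
#' @param clinical The clinical table (see \code{\link{clinical_table}}).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return Object of class \code{adwm_calibration}: \code{slope},
#'   \code{intercept}, \code{r2}, \code{p}, \code{degree}, \code{fit},
#'   \code{data}, \code{per_week} (data frame of week sub-fits).
#' @export
correlate_clinical <- function(spans, clinical = clinical_table(), degree = 1) {
  if (!degree %in% 1:2) stop("`degree` must be 1 or 2")
  x <- if (is.list(spans)) vapply(spans, `[[`, numeric(1), "mean_span") else
    as.numeric(spans)
  if (length(x) != nrow(clinical))
    stop("need one span per clinical record (", nrow(clinical), ")")
  if (length(x) < 3) stop("insufficient data: need at least 3 points")
  if (stats::sd(x) == 0)
    stop("degenerate input: zero span variance, slope undefined")
  df <- data.frame(span = x, adascog = clinical$adascog_effect,
                   weeks = clinical$weeks)
  fit <- stats::lm(adascog ~ poly(span, degree, raw = TRUE), data = df)
  sm <- suppressWarnings(summary(fit))  # collinear toy inputs warn harmlessly
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  per_week <- do.call(rbind, lapply(c(12, 26, 52), function(w) {
    sel <- df$weeks == w
    if (sum(sel) < 3 || stats::sd(df$span[sel]) == 0)
      return(data.frame(week = w, n = sum(sel), slope = NA, r2 = NA, p = NA))
    fw <- stats::lm(adascog ~ span, data = df[sel, ])
    sw <- suppressWarnings(summary(fw))
    data.frame(week = w, n = sum(sel), slope = stats::coef(fw)[2],
               r2 = sw$r.squared,
               p = stats::coef(sw)[2, 4])
  }))
  rownames(per_week) <- NULL
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared, p = unname(p), degree = degree,
                 fit = fit, data = df, per_week = per_week),
            class = "adwm_calibration")
}

#' @export
print.adwm_calibration <- function(x, ...) {
  cat(sprintf("<calibration> degree %d: r2 = %.3f, slope = %.2f ADAS-Cog pts per span-second, p = %.3g\n",
              x$degree, x$r2, x$slope, x$p))
  print(x$per_week, digits = 3)
  invisible(x)
}

#' Two-level DOE screen of the free parameters
#'
#' Evaluates the response on a 2n-run two-level design built from fold-over
#' pairs (run k: factor k high, all others low; run n+k: the mirrored
#' complement), estimates each factor's main effect as the difference of
#' mean responses at its high and low settings, and returns the effects
#' ranked by magnitude (the Pareto ranking used to identify calibration
#' drivers).
#'
#' @param params Named list of two-element ranges \code{c(low, high)} with
#'   distinct values.
#' @param response Function of a named parameter vector returning a scalar.
#' @return Object of class \code{adwm_doe}: \code{design} (with the
#'   response column), \code{effects} (named, original order),
#'   \code{pareto} (data frame ranked by |effect|), \code{n_runs}.
#' @export
doe_screen <- function(params, response) {
  n <- length(params)
  if (n < 1) stop("no parameters")
  if (any(vapply(params, function(r) length(r) != 2 || r[1] == r[2], logical(1))))
    stop("every range needs distinct low/high values")
  nm <- names(params)
  design <- matrix(-1, 2 * n, n, dimnames = list(NULL, nm))
  for (k in seq_len(n)) {
    design[k, ] <- -1; design[k, k] <- 1          # factor k high, rest low
    design[n + k, ] <- 1; design[n + k, k] <- -1  # fold-over
  }
  vals <- t(apply(design, 1, function(s) {
    vapply(seq_len(n), function(j)
      if (s[j] > 0) params[[j]][2] else params[[j]][1], numeric(1))
  }))
  colnames(vals) <- nm
  y <- apply(vals, 1, function(v) response(stats::setNames(v, nm)))
  bad <- !is.finite(y)
  if (any(bad))
    warning(sum(bad), " design point(s) returned non-finite responses; ",
            "effects computed on the remaining runs")
  effects <- vapply(seq_len(n), function(j) {
    hi <- design[, j] > 0 & !bad
    lo <- design[, j] < 0 & !bad
    mean(y[hi]) - mean(y[lo])
  }, numeric(1))
  names(effects) <- nm
  pareto <- data.frame(param = nm, effect = effects,
                       abs_effect = abs(effects))
  pareto <- pareto[order(-pareto$abs_effect), ]
  rownames(pareto) <- NULL
  structure(list(design = cbind(as.data.frame(vals), response = y),
                 effects = effects, pareto = pareto, n_runs = 2L * n),
            class = "adwm_doe")
}

#' @export
print.adwm_doe <- function(x, ...) {
  cat(sprintf("<DOE screen> %d runs, Pareto ranking of main effects:\n", x$n_runs))
  print(x$pareto, digits = 4)
  invisible(x)
}

#' Response-surface refinement of a parameter vector
#'
#' Local optimisation of a (possibly noisy) response: at each iteration a
#' star design (center plus axial points at +/- delta per dimension) is
#' evaluated, a separable quadratic surface fitted, and the step taken to
#' the surface optimum within the trust region; the region shrinks when no
#' improvement is found.  Maximises the response; every evaluation is
#' recorded in the trace and the total never exceeds \code{budget}.
#'
#' @param start Named numeric parameter vector.
#' @param response Function of a named vector returning a scalar to
#'   maximise.
#' @param budget Maximum number of response evaluations, at least 1.
#' @param delta_frac Initial trust-region half-width as a fraction of
#'   \code{abs(start)} (scale 1 for zero entries).
#' @return Object of class \code{adwm_rsm}: \code{best} (named vector),
#'   \code{best_value}, \code{trace} (data frame of all evaluations),
#'   \code{n_evals}.
#' @export
optimize_response_surface <- function(start, response, budget = 50,
                                      delta_frac = 0.2) {
  if (budget < 1) stop("`budget` must be at least 1")
  nm <- names(start)
  n <- length(start)
  trace <- list()
  n_evals <- 0L
  evalr <- function(p) {
    n_evals <<- n_evals + 1L
    v <- response(stats::setNames(p, nm))
    trace[[n_evals]] <<- c(p, value = v)
    v
  }
  best <- as.numeric(start)
  best_v <- evalr(best)
  delta <- ifelse(best == 0, 1, abs(best)) * delta_frac
  while (n_evals + 2 * n <= budget) {
    yp <- numeric(n); ym <- numeric(n)
    for (j in seq_len(n)) {
      pp <- best; pp[j] <- pp[j] + delta[j]; yp[j] <- evalr(pp)
      pm <- best; pm[j] <- pm[j] - delta[j]; ym[j] <- evalr(pm)
    }
    # separable quadratic through (center, +delta, -delta) per dimension
    b <- (yp - ym) / (2 * delta)
    a <- (yp + ym - 2 * best_v) / (delta^2)
    step <- ifelse(is.finite(a) & a < 0, -b / (2 * a) * 2, sign(b) * delta)
    step <- pmax(pmin(step, delta), -delta)
    cand <- best + step
    if (n_evals >= budget) break
    cand_v <- evalr(cand)
    axis_best <- max(c(yp, ym))
    if (cand_v >= best_v) {
      best <- cand; best_v <- cand_v
      # grow the trust region when the step was clamped at its boundary
      hit <- abs(step) >= delta * 0.99
      delta[hit] <- delta[hit] * 2
    } else if (axis_best > best_v) {
      k <- which.max(c(yp, ym))
      j <- ((k - 1) %% n) + 1
      best[j] <- best[j] + if (k <= n) delta[j] else -delta[j]
      best_v <- axis_best
    } else {
      delta <- delta / 2
      if (all(delta < 1e-10)) break
    }
  }
  tr <- as.data.frame(do.call(rbind, trace))
  structure(list(best = stats::setNames(best, nm), best_value = best_v,
                 trace = tr, n_evals = n_evals),
            class = "adwm_rsm")
}

#' @export
print.adwm_rsm <- function(x, ...) {
  cat(sprintf("<response surface> best value %.6g after %d evaluations\n",
              x$best_value, x$n_evals))
  print(round(x$best, 6))
  invisible(x)
}

#' One-at-a-time sensitivity scan
#'
#' Evaluates the response along one parameter with all others held at the
#' base vector.
#'
#' @param param Name of the scanned parameter.
#' @param values Values to scan (non-empty).
#' @param base Named base parameter vector.
#' @param response Function of a named vector returning a scalar.
#' @return Data frame with columns \code{value} and \code{response}.
#' @export
sensitivity_scan <- function(param, values, base, response) {
  if (!length(values)) stop("`values` must be non-empty")
  if (!param %in% names(base)) stop("unknown parameter: ", param)
  out <- vapply(values, function(v) {
    p <- base; p[param] <- v
    response(p)
  }, numeric(1))
  data.frame(value = values, response = out)
}
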