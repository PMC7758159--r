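# End-to-end workflows: SSNA spike quantification and CVNA burst
# quantification, plus group statistics on per-animal summary tables.

#' Pipeline configuration
#'
#' Collects every tunable of the two analysis chains. Unknown keys are
#' rejected so configuration typos fail loudly.
#'
#' @param nerve_channel Name of the nerve channel; default `"nerve"`.
#' @param bp_channel Name of the blood-pressure channel or `NULL`;
#'   default `"bp"`.
#' @param ssna_filters,cvna_filters Filter chains (lists of
#'   [filter_spec()]); defaults [ssna_filter_specs()] /
#'   [cvna_filter_specs()].
#' @param spike_k Spike threshold multiplier; default 3.
#' @param refractory_s Spike refractory period in seconds; default 0.001.
#' @param tau Integrator time constant in seconds; default 0.1.
#' @param burst_k Envelope threshold multiplier; default 2.
#' @param min_separation_s Envelope peak separation in seconds; default 0.1.
#' @param merge_gap_s Burst merge gap in seconds; default 0.3.
#' @param bin_s Analysis bin in seconds; default 600.
#' @param postmortem_label Annotation label of the noise segment; default
#'   `"postmortem"`.
#' @param seed Seed recorded in outputs; default 1.
#' @param ... Unknown keys (rejected).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(nerve_channel = "nerve", bp_channel = "bp",
                            ssna_filters = ssna_filter_specs(),
                            cvna_filters = cvna_filter_specs(),
                            spike_k = 3, refractory_s = 0.001, tau = 0.1,
                            burst_k = 2, min_separation_s = 0.1,
                            merge_gap_s = 0.3, bin_s = 600,
                            postmortem_label = "postmortem", seed = 1L,
                            ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  cfg <- list(nerve_channel = nerve_channel, bp_channel = bp_channel,
              ssna_filters = ssna_filters, cvna_filters = cvna_filters,
              spike_k = spike_k, refractory_s = refractory_s, tau = tau,
              burst_k = burst_k, min_separation_s = min_separation_s,
              merge_gap_s = merge_gap_s, bin_s = bin_s,
              postmortem_label = postmortem_label, seed = seed)
  structure(cfg, class = "pipeline_config")
}

# Polynomial rolling hash over the serialized configuration, for
# reproducibility stamps (not cryptographic).
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

validate_pipeline_inputs <- function(rec, postmortem, config) {
  fs <- rec$fs
  for (sp in c(config$ssna_filters, config$cvna_filters))
    filter_coefs(sp, fs) # errors early on e.g. band edge >= Nyquist
  if (!config$nerve_channel %in% names(rec$channels))
    stop("recording has no channel `", config$nerve_channel, "`",
         call. = FALSE)
  get_annotation(postmortem, config$postmortem_label) # errors if missing
  invisible(TRUE)
}

#' Run the SSNA or CVNA quantification pipeline
#'
#' `mode = "ssna"`: notch + band-pass filter the nerve channel, estimate
#' the noise floor from the post-mortem recording put through the same
#' chain, detect spikes at `spike_k` times the floor, and summarize firing
#' frequency and amplitude gain per bin.
#'
#' `mode = "cvna"`: band-pass with the stricter chain, rectify-integrate
#' with time constant `tau`, reference the envelope to the integrated
#' post-mortem median, detect envelope peaks, merge them into activation
#' bursts and count bursts per bin.
#'
#' @param rec A [recording()] to quantify.
#' @param postmortem A [recording()] carrying the annotation named by
#'   `config$postmortem_label`, used for the noise reference.
#' @param config A [pipeline_config()].
#' @param mode `"ssna"` or `"cvna"`.
#' @param window Analysis span `c(t_start, t_end)` in seconds; default the
#'   full recording.
#' @param out_dir If non-`NULL`, write `events` and `bins` JSON/CSV files
#'   there.
#' @return List with `mode`, `config_hash`, `seed`, `noise`, the detected
#'   `events` (spikes or bursts), per-bin `bins`, and `bp_summary` when a
#'   blood-pressure channel is present.
#' @export
run_pipeline <- function(rec, postmortem, config = pipeline_config(),
                         mode = c("ssna", "cvna"),
                         window = c(0, rec_duration(rec)), out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "recording"), inherits(postmortem, "recording"),
            inherits(config, "pipeline_config"))
  validate_pipeline_inputs(rec, postmortem, config)
  fs <- rec$fs
  pm_ann <- get_annotation(postmortem, config$postmortem_label)
  pm_raw <- rec_channel(postmortem, config$nerve_channel)
  x <- rec_channel(rec, config$nerve_channel)
  if (mode == "ssna") {
    xf <- apply_filter_chain(x, fs, config$ssna_filters)
    pmf <- apply_filter_chain(pm_raw, fs, config$ssna_filters)
    noise <- estimate_noise_floor(pmf, fs, pm_ann)
    spikes <- detect_spikes(xf, fs, noise, k = config$spike_k,
                            refractory_s = config$refractory_s)
    spikes <- spikes[spikes$t >= window[1] & spikes$t < window[2], ,
                     drop = FALSE]
    bins <- spike_bin_summary(spikes, noise, window, config$bin_s)
    events <- spikes
    noise_ref <- noise$floor
  } else {
    xf <- apply_filter_chain(x, fs, config$cvna_filters)
    pmf <- apply_filter_chain(pm_raw, fs, config$cvna_filters)
    env <- rectify_integrate(xf, fs, config$tau)
    pm_env <- rectify_integrate(pmf, fs, config$tau)
    noise_ref <- envelope_noise_ref(pm_env)
    peaks <- detect_integrated_peaks(env, noise_ref, k = config$burst_k,
                                     min_separation_s =
                                       config$min_separation_s)
    bursts <- merge_peaks_to_bursts(peaks, config$merge_gap_s)
    bursts <- bursts[bursts$t_start >= window[1] &
                       bursts$t_start < window[2], , drop = FALSE]
    bins <- bin_burst_count(bursts, window, config$bin_s)
    events <- bursts
  }
  bp_summary <- NULL
  if (!is.null(config$bp_channel) &&
      config$bp_channel %in% names(rec$channels))
    bp_summary <- bp_bin_summary(rec_channel(rec, config$bp_channel), fs,
                                 config$bin_s)
  out <- list(mode = mode, config_hash = config_hash(config),
              seed = config$seed, noise_ref = noise_ref, events = events,
              bins = bins, bp_summary = bp_summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- list(mode = mode, config_hash = out$config_hash,
                  seed = config$seed)
    jsonlite::write_json(c(stamp, list(events = events)),
                         file.path(out_dir, paste0(mode, "_events.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(c(stamp, list(bins = bins)),
                         file.path(out_dir, paste0(mode, "_bins.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    data.table::fwrite(bins, file.path(out_dir, paste0(mode, "_bins.csv")))
  }
  out
}

#' Group statistics on a per-animal summary table
#'
#' Dispatches on the design: a table with a 2-level `group` column gets the
#' pooled two-sample t test; a table with `factor_a` and `factor_b`
#' columns gets the two-way cell-means ANOVA with Tukey-Kramer post hoc.
#'
#' @param table Data frame with `value` plus either `group` (2 levels) or
#'   `factor_a` and `factor_b`.
#' @param out_file If non-`NULL`, write the results there as CSV.
#' @return Data frame of test results (`comparison`, `statistic`, `df`,
#'   `p`).
#' @export
run_group_stats <- function(table, out_file = NULL) {
  stopifnot(is.data.frame(table), "value" %in% names(table))
  if (all(c("factor_a", "factor_b") %in% names(table))) {
    res <- two_way_anova_tukey(table$value, table$factor_a, table$factor_b)
  } else if ("group" %in% names(table)) {
    g <- factor(table$group)
    if (nlevels(g) != 2)
      stop("t test requires exactly 2 groups; give `factor_a`/`factor_b` ",
           "for multi-group designs", call. = FALSE)
    if (any(table(g) < 2)) stop("each group needs n >= 2", call. = FALSE)
    sp <- split(table$value, g)
    res <- t_test_two_sample(sp[[1]], sp[[2]], labels = levels(g))
  } else {
    stop("table must contain `group` or `factor_a`/`factor_b`",
         call. = FALSE)
  }
  if (!is.null(out_file)) data.table::fwrite(res, out_file)
  res
}
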