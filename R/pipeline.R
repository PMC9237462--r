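## 32-bit FNV-1a hash of a string; stamps every pipeline artifact with the
## configuration that produced it.
fnv1a <- function(s) {
  h <- 0x811c9dc5
  prime <- 16777619
  for (b in utf8ToInt(s)) {
    # xor on the low 16 bits (h itself can exceed the integer range)
    h <- bitwXor(h %% 65536, b %% 65536) + (h %/% 65536) * 65536
    # 32-bit modular multiply in two 16-bit halves (doubles lose bits
    # beyond 2^53)
    lo <- (h %% 65536) * prime
    hi <- ((h %/% 65536) * prime) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Build a validated pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] with its default;
#' unknown keys are rejected so typos cannot silently fall back to
#' defaults. Every random stage is driven by the single `seed`.
#'
#' @param ... Named overrides of the defaults (see Details).
#' @details Recognised keys: `n_participants`, `conditions`, `reps`,
#'   `fillers`, `blocks`, `coupling`, `jitter_base_ms`, `n_channels`,
#'   `noise_amp`, `kernel_gain`, `surrogates`, `harmonics`, `fmax`,
#'   `seed`, `out_dir`, `schema`.
#' @return A list of class `run_config` with a `hash` attribute.
#' @export
run_config <- function(...) {
  defaults <- list(
    n_participants = 25L, conditions = condition_labels(), reps = 10L,
    fillers = 50L, blocks = 5L, coupling = 1, jitter_base_ms = 2,
    n_channels = 32L, noise_amp = 8, kernel_gain = 4,
    surrogates = 5000L, harmonics = c(4, 8, 12, 16), fmax = 26,
    seed = 1L, out_dir = NULL, schema = "sylentrain-run-v1"
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  # hash the scientific parameters only: where the artifacts are written
  # must not change their fingerprint
  fp <- cfg[setdiff(sort(names(cfg)), "out_dir")]
  attr(cfg, "hash") <- fnv1a(jsonlite::toJSON(fp, auto_unbox = TRUE,
                                              digits = NA))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline end to end
#'
#' Synthesises a study ([make_study()]), runs the ITPC averaging hierarchy
#' and surrogate-null significance at the stimulus harmonics, the ITPC and
#' edge-marker PCAs, condition clustering, phoneme-group comparisons
#' (when the full condition set is present) and the marker-ITPC
#' correlations. When `out_dir` is set, tidy CSVs and a JSON report (all
#' stamped with the config hash) are written there.
#'
#' @param cfg A [run_config()] (or arguments to build one).
#' @return A report list, invisibly when writing to disk.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  hash <- attr(cfg, "hash")
  study <- make_study(
    n_participants = cfg$n_participants, conditions = cfg$conditions,
    reps = cfg$reps, fillers = cfg$fillers, blocks = cfg$blocks,
    coupling = cfg$coupling, jitter_base_ms = cfg$jitter_base_ms,
    cfg = eeg_sim_config(n_channels = cfg$n_channels,
                         noise_amp = cfg$noise_amp,
                         kernel_gain = cfg$kernel_gain),
    fmax = cfg$fmax, seed = cfg$seed)
  avg <- average_hierarchy(study$itpc)
  n_streams <- nrow(study$itpc$stream_info)
  null <- surrogate_null(n_streams = n_streams,
                         n_electrodes = cfg$n_channels, K = cfg$reps,
                         n_fictive = cfg$surrogates, seed = cfg$seed + 7L)
  real_h <- harmonic_extract(avg$R_fa, avg$freqs, cfg$harmonics)
  sig <- lapply(seq_along(cfg$harmonics), function(i)
    peak_significance(real_h[i, ], null))
  names(sig) <- paste0("f", cfg$harmonics)
  itpc_df <- study_itpc_conditions(study, cfg$harmonics)
  comp <- itpc_components(itpc_df)
  cond_scores <- stats::aggregate(
    comp$scores[, c("ITPC1", "ITPC2")],
    by = list(condition = comp$scores$condition), FUN = mean)
  cs <- as.matrix(cond_scores[, c("ITPC1", "ITPC2")])
  rownames(cs) <- cond_scores$condition
  clusters <- if (nrow(cs) >= 3L)
    kmeans_conditions(cs, k = 3L, seed = cfg$seed) else NULL
  groups <- NULL
  if (all(unlist(phoneme_groups()$three) %in% cfg$conditions)) {
    groups <- lapply(phoneme_groups(), function(part) {
      ga <- group_aggregate(comp$scores, part, value = "ITPC1")
      an <- rm_anova_gg(ga$by_participant)
      ph <- bonferroni_posthoc(ga$by_participant)
      list(summary = ga$summary, anova = an, posthoc = ph)
    })
  }
  marker_cols <- c("sharpness", "ma", "ma_latency", "ma80_latency",
                   "plateau", "md", "md_latency", "gini")
  cors <- NULL
  mpc <- NULL
  if (nrow(cond_scores) >= 3L) {
    mk <- study$markers[match(cond_scores$condition,
                              study$markers$condition), ]
    cors <- do.call(rbind, lapply(marker_cols, function(mc) {
      pc <- pearson_cor(cond_scores$ITPC1, mk[[mc]])
      data.frame(marker = mc, r = pc$r, p = pc$p.value)
    }))
    f4 <- stats::aggregate(f4 ~ condition, data = itpc_df, FUN = mean)
    f4 <- f4[match(cond_scores$condition, f4$condition), ]
    md_cor <- pearson_cor(f4$f4, mk$md_latency)
    cors <- rbind(cors, data.frame(marker = "md_latency_vs_f4",
                                   r = md_cor$r, p = md_cor$p.value))
    if (nrow(mk) > 5L) mpc <- marker_components(mk)
  }
  report <- list(config = unclass(cfg), hash = hash,
                 significance = sig,
                 itpc_explained = comp$explained,
                 itpc_loadings = comp$loadings,
                 condition_scores = cond_scores,
                 clusters = clusters, groups = groups,
                 marker_correlations = cors,
                 marker_pca = if (!is.null(mpc))
                   list(explained = mpc$explained,
                        loadings = mpc$loadings) else NULL,
                 null_q95 = stats::quantile(null$values, 0.95,
                                            names = FALSE))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) {df$config_hash <- hash; df}
    utils::write.csv(stamp(itpc_df),
                     file.path(cfg$out_dir, "itpc_conditions.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(comp$scores),
                     file.path(cfg$out_dir, "itpc_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(study$markers),
                     file.path(cfg$out_dir, "markers.csv"),
                     row.names = FALSE)
    if (!is.null(cors))
      utils::write.csv(stamp(cors),
                       file.path(cfg$out_dir, "correlations.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(hash = hash,
           significance = lapply(sig, function(s)
             list(U = s$statistic, p = s$p.value)),
           itpc_explained = comp$explained,
           null_q95 = report$null_q95,
           marker_correlations = cors,
           seed = cfg$seed),
      file.path(cfg$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
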