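#' Build train and transfer dataset groups
#'
#' Generates five labelled dataset groups with the site/year provenance
#' structure used for transferability evaluation: `train`; `A` = same
#' sites as train but a different year; `B` = different sites, same year;
#' `C` = different sites and different year; `D` = a disjoint region,
#' emulated by drawing its site frequency effects from a shifted, wider
#' distribution (and optionally a different SNR). Each group contains one
#' recording per site; a fixed fraction of recordings contains calls and
#' the rest are call-free (with 8 sites, 5 recordings with calls and 3
#' without).
#'
#' @param config a [scene_config()]; `n_sites` is the number of recordings
#'   per group and must be >= 2.
#' @param seed integer RNG seed.
#' @param audio generate waveforms (`TRUE`) or annotations only.
#' @param n_call_recordings recordings per group that contain calls;
#'   default `round(5/8 * n_sites)` (clamped to `[1, n_sites - 1]`) so
#'   every group mixes recordings with and without calls.
#' @param snr_db_by_group optional named numeric vector (names among
#'   `train, A, B, C, D`) overriding `config$snr_db` per group.
#'
#' @return A named list of `"dataset_group"` objects, each with elements
#'   `label`, `recordings`, `annotations`, `site_effects`, and provenance
#'   flags `same_sites`, `same_year`, `same_region`.
#' @export
build_dataset_groups <- function(config, seed = config$seed, audio = TRUE,
                                 n_call_recordings = NULL,
                                 snr_db_by_group = NULL) {
  validate_scene_config(config)
  if (config$n_sites < 2L)
    stop("insufficient sites: build_dataset_groups needs n_sites >= 2")
  n <- config$n_sites
  if (is.null(n_call_recordings))
    n_call_recordings <- min(n - 1L, max(1L, round(5 / 8 * n)))
  if (n_call_recordings < 1L || n_call_recordings >= n + 1L)
    stop("n_call_recordings must be in [1, n_sites]")

  set.seed(as.integer(seed))
  sub_seed <- sample.int(.Machine$integer.max, 6L)

  defs <- list(
    train = list(sites = paste0("T", seq_len(n)), year = "Y1",
                 same_sites = TRUE, same_year = TRUE, same_region = TRUE),
    A = list(sites = paste0("T", seq_len(n)), year = "Y2",
             same_sites = TRUE, same_year = FALSE, same_region = TRUE),
    B = list(sites = paste0("B", seq_len(n)), year = "Y1",
             same_sites = FALSE, same_year = TRUE, same_region = TRUE),
    C = list(sites = paste0("C", seq_len(n)), year = "Y2",
             same_sites = FALSE, same_year = FALSE, same_region = TRUE),
    D = list(sites = paste0("D", seq_len(n)), year = "Y3",
             same_sites = FALSE, same_year = FALSE, same_region = FALSE)
  )

  # one recording per site; which recordings carry calls is drawn once per
  # group, so each group has n_call_recordings with calls, rest without
  train_effects <- NULL
  groups <- list()
  for (i in seq_along(defs)) {
    label <- names(defs)[i]
    d <- defs[[i]]
    cfg <- config
    if (!is.null(snr_db_by_group) && label %in% names(snr_db_by_group))
      cfg$snr_db <- unname(snr_db_by_group[label])
    cfg$recordings_per_site <- 1L
    set.seed(sub_seed[i])
    with_calls <- sample.int(n, n_call_recordings)
    lambda_vec <- ifelse(seq_len(n) %in% with_calls,
                         config$calls_per_recording, 0)
    site_eff <- if (label == "A") train_effects else NULL
    if (label == "D") {
      # disjoint region: shifted, wider site-effect distribution
      e <- stats::rnorm(n, 2 * config$sd_site_hz, 1.5 * config$sd_site_hz)
      names(e) <- d$sites
      site_eff <- e
    }
    sc <- synth_scene(cfg, seed = sub_seed[i], audio = audio,
                      site_ids = d$sites, site_effects = site_eff,
                      year_label = d$year, group_label = label,
                      recording_prefix = label,
                      calls_per_recording_vec = lambda_vec,
                      ensure_calls = TRUE)
    if (label == "train") train_effects <- sc$site_effects
    groups[[label]] <- structure(
      list(label = label, recordings = sc$recordings,
           annotations = sc$annotations, site_effects = sc$site_effects,
           same_sites = d$same_sites, same_year = d$same_year,
           same_region = d$same_region),
      class = "dataset_group")
  }
  groups
}

#' @export
print.dataset_group <- function(x, ...) {
  cat(sprintf(
    "Dataset group '%s': %d recordings, %d calls (same_sites=%s, same_year=%s, same_region=%s)\n",
    x$label, length(x$recordings), nrow(x$annotations),
    x$same_sites, x$same_year, x$same_region))
  invisible(x)
}
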