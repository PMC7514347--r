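#' Simulate a driven branching process
#'
#' Canonical driven Galton--Watson process with Poisson offspring and Poisson
#' drive: `a_(t+1) ~ Poisson(sigma * a_t + drive_t)`. For `sigma < 1` the
#' stationary mean is `drive / (1 - sigma)`. Optional per-event binomial
#' subsampling emulates observing only a fraction of the population's spikes,
#' and optional injected non-stationarities exercise the rejection step of
#' the branching analysis:
#' * `list(type = "drift", factor = f)` ramps the drive linearly from
#'   `drive` to `f * drive` across the series;
#' * `list(type = "updown", period = n, low = l, high = h)` alternates the
#'   drive between `l` and `h` every `n/2` bins (up/down-state switching).
#'
#' @param sigma branching ratio (>= 0; `sigma >= 1` with positive drive is
#'   super-critical and flagged with a warning — the series may grow without
#'   bound).
#' @param drive expected external events per bin.
#' @param n_bins series length.
#' @param a0 initial activity; defaults to the rounded stationary mean (or
#'   `round(drive)` when `sigma >= 1`).
#' @param subsample_prob probability of observing each event (1 = full
#'   observation).
#' @param nonstationarity `NULL` or a list as described above.
#' @param bin_width nominal bin width in seconds (default 0.016).
#' @param seed optional seed; the series is fully determined by it.
#' @return a `cm_activity` series of observed counts.
#' @export
simulate_branching <- function(sigma, drive, n_bins, a0 = NULL,
                               subsample_prob = 1, nonstationarity = NULL,
                               bin_width = 0.016, seed = NULL) {
  stopifnot(sigma >= 0, drive >= 0, n_bins >= 1,
            subsample_prob > 0, subsample_prob <= 1)
  if (sigma >= 1 && drive > 0)
    warning("sigma >= 1 with positive drive: super-critical, series may grow")
  if (!is.null(seed)) set.seed(seed)
  drv <- rep(drive, n_bins)
  if (!is.null(nonstationarity)) {
    drv <- switch(nonstationarity$type,
      drift = drive * seq(1, nonstationarity$factor, length.out = n_bins),
      updown = {
        half <- max(1L, as.integer(nonstationarity$period) %/% 2L)
        phase <- ((seq_len(n_bins) - 1L) %/% half) %% 2L
        ifelse(phase == 0L, nonstationarity$low, nonstationarity$high)
      },
      stop("unknown nonstationarity type"))
  }
  if (is.null(a0))
    a0 <- if (sigma < 1) round(drive / (1 - sigma)) else round(drive)
  a <- integer(n_bins)
  prev <- a0
  for (t in seq_len(n_bins)) {
    prev <- stats::rpois(1L, sigma * prev + drv[t])
    a[t] <- prev
  }
  obs <- if (subsample_prob < 1) stats::rbinom(n_bins, a, subsample_prob) else a
  activity_series(obs, bin_width)
}

#' Scatter binned counts into spike times
#'
#' Each bin's count is placed as uniformly timed spikes within the bin and
#' assigned to units uniformly (multinomially). Spike times are kept strictly
#' inside their bin so that re-binning with [bin_bout()] returns the original
#' counts exactly.
#'
#' @param series a `cm_activity`.
#' @param n_units number of units to distribute spikes over.
#' @param t_start absolute start time of the series (seconds).
#' @param seed optional seed.
#' @return data.frame with columns `unit`, `time`, sorted by time.
#' @export
spikes_from_counts <- function(series, n_units, t_start = 0, seed = NULL) {
  stopifnot(inherits(series, "cm_activity"), n_units >= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- series$counts
  bw <- series$bin_width
  total <- sum(counts)
  if (total == 0L)
    return(data.frame(unit = integer(0), time = numeric(0)))
  bin_of <- rep.int(seq_along(counts), counts)
  # offsets kept away from the bin edges so floating-point re-binning is exact
  u <- stats::runif(total, 1e-6, 1 - 1e-6)
  time <- t_start + bw * (bin_of - 1 + u)
  unit <- sample.int(n_units, total, replace = TRUE)
  df <- data.frame(unit = unit, time = time)
  df[order(df$time), , drop = FALSE]
}

#' Generate a full synthetic conditioning cohort
#'
#' Writes a directory of spike files, bout tables, a subject manifest and a
#' behaviour table emulating a contextual-fear-conditioning study: `n_cfc`
#' conditioned and `n_sham` sham subjects, each with a baseline and a
#' post-conditioning epoch of slow-wave-sleep bouts. Per-bout activity is a
#' subsampled driven branching process; conditioned subjects are drawn with
#' a larger post-conditioning drop in the branching ratio and higher
#' learning scores than sham subjects. Defaults: baseline sigma 0.99 for
#' both groups (near-critical), post-conditioning shift -0.05 (CFC) and
#' -0.01 (Sham); bouts log-uniform 2--10 minutes.
#'
#' Identical parameters and seed produce byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param n_cfc,n_sham subjects per condition (defaults 5 and 3).
#' @param bouts_per_epoch SWS bouts per subject and epoch (default 10).
#' @param sigma named list of branching ratios per condition and epoch:
#'   `cfc_baseline`, `cfc_post`, `sham_baseline`, `sham_post`.
#' @param bout_minutes range of bout durations (minutes, log-uniform).
#' @param drive external drive per 16 ms bin of the underlying process.
#' @param subsample_prob fraction of population events observed.
#' @param n_units recorded units per subject.
#' @param bin_width bin width in seconds.
#' @param freezing named list of freezing-percentage ranges:
#'   `baseline` (both groups), `cfc_test`, `sham_test`.
#' @param seed integer seed.
#' @return the manifest data.frame (invisibly); files written under
#'   `out_dir`: `<subject>_<epoch>_spikes.tsv`, `<subject>_bouts.tsv`,
#'   `manifest.csv`, `behavior.csv`, `cohort.json` (parameters).
#' @export
make_cohort <- function(out_dir, n_cfc = 5, n_sham = 3, bouts_per_epoch = 10,
                        sigma = list(cfc_baseline = 0.99, cfc_post = 0.94,
                                     sham_baseline = 0.99, sham_post = 0.98),
                        bout_minutes = c(2, 10), drive = 0.04,
                        subsample_prob = 0.1, n_units = 15,
                        bin_width = 0.016,
                        freezing = list(baseline = c(5, 15),
                                        cfc_test = c(45, 70),
                                        sham_test = c(5, 20)),
                        seed = 1) {
  stopifnot(n_cfc >= 1, n_sham >= 1, bouts_per_epoch >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  subjects <- data.frame(
    subject = sprintf("m%02d", seq_len(n_cfc + n_sham)),
    condition = c(rep("CFC", n_cfc), rep("Sham", n_sham)))
  manifest <- list(); behavior <- list()
  for (i in seq_len(nrow(subjects))) {
    sj <- subjects$subject[i]
    cond <- subjects$condition[i]
    key <- tolower(cond)
    bout_rows <- list()
    for (epoch in c("baseline", "post_cond")) {
      sig_true <- sigma[[paste0(key, "_",
                                if (epoch == "baseline") "baseline" else "post")]]
      dur_min <- exp(stats::runif(bouts_per_epoch, log(bout_minutes[1]),
                                  log(bout_minutes[2])))
      gap <- stats::runif(bouts_per_epoch, 60, 600)
      # post-conditioning recording day starts 24 h after baseline onset
      offset <- if (epoch == "baseline") 0 else 86400
      start <- offset + cumsum(gap + c(0, 60 * dur_min[-bouts_per_epoch]))
      end <- start + 60 * dur_min
      spk <- list()
      for (b in seq_len(bouts_per_epoch)) {
        n_bins <- floor(60 * dur_min[b] / bin_width)
        series <- simulate_branching(sig_true, drive, n_bins,
                                     subsample_prob = subsample_prob,
                                     bin_width = bin_width)
        spk[[b]] <- spikes_from_counts(series, n_units, t_start = start[b])
      }
      spikes <- do.call(rbind, spk)
      spike_file <- file.path(out_dir, sprintf("%s_%s_spikes.tsv", sj, epoch))
      data.table::fwrite(spikes, spike_file, sep = "\t")
      bout_rows[[epoch]] <- data.frame(start = start, end = end, epoch = epoch)
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject = sj, condition = cond, epoch = epoch,
        spike_file = basename(spike_file),
        bout_file = sprintf("%s_bouts.tsv", sj))
    }
    bouts <- do.call(rbind, bout_rows)
    data.table::fwrite(bouts, file.path(out_dir, sprintf("%s_bouts.tsv", sj)),
                       sep = "\t")
    fb <- stats::runif(1, freezing$baseline[1], freezing$baseline[2])
    ft <- if (cond == "CFC")
      stats::runif(1, freezing$cfc_test[1], freezing$cfc_test[2])
    else stats::runif(1, freezing$sham_test[1], freezing$sham_test[2])
    behavior[[length(behavior) + 1L]] <- data.frame(
      subject = sj, condition = cond,
      freeze_baseline_pct = fb, freeze_test_pct = ft,
      learning_score = learning_score(ft, fb))
  }
  manifest <- do.call(rbind, manifest)
  behavior <- do.call(rbind, behavior)
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
  data.table::fwrite(behavior, file.path(out_dir, "behavior.csv"))
  jsonlite::write_json(
    list(n_cfc = n_cfc, n_sham = n_sham, bouts_per_epoch = bouts_per_epoch,
         sigma = sigma, bout_minutes = bout_minutes, drive = drive,
         subsample_prob = subsample_prob, n_units = n_units,
         bin_width = bin_width, seed = seed),
    file.path(out_dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort directory into spike datasets
#'
#' Reads the manifest written by [make_cohort()] (or any directory using the
#' same layout) and assembles one [spike_dataset()] per subject, combining
#' the baseline and post-conditioning epochs.
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return named list of `cm_spike_dataset` objects, with the behaviour
#'   table attached as attribute `"behavior"` when present.
#' @export
read_cohort <- function(dir) {
  manifest <- data.table::fread(file.path(dir, "manifest.csv"),
                                data.table = FALSE)
  out <- list()
  for (sj in unique(manifest$subject)) {
    rows <- manifest[manifest$subject == sj, , drop = FALSE]
    spikes <- do.call(rbind, lapply(rows$spike_file, function(f)
      data.table::fread(file.path(dir, f), data.table = FALSE)))
    bouts <- data.table::fread(file.path(dir, rows$bout_file[1]),
                               data.table = FALSE)
    out[[sj]] <- spike_dataset(spikes, bouts, subject_id = sj,
                               condition = rows$condition[1])
  }
  beh_file <- file.path(dir, "behavior.csv")
  if (file.exists(beh_file))
    attr(out, "behavior") <- data.table::fread(beh_file, data.table = FALSE)
  out
}

#' Run the full branching pipeline on a cohort directory
#'
#' Reads every subject, estimates per-epoch branching parameters
#' ([subject_sigma()]), joins the behaviour table, and summarises the
#' per-group change ([group_change_summary()]).
#'
#' @param dir cohort directory.
#' @param ... passed to [subject_sigma()].
#' @return list with `subjects` (per-subject table: condition, per-epoch
#'   sigma and sem, `delta_sigma`, learning score) and `groups` (the group
#'   change summary).
#' @export
analyze_cohort <- function(dir, ...) {
  datasets <- read_cohort(dir)
  behavior <- attr(datasets, "behavior")
  rows <- lapply(datasets, function(ds) {
    ss <- subject_sigma(ds, ...)
    ep <- ss$epochs
    base <- ep[ep$epoch == "baseline", , drop = FALSE]
    post <- ep[ep$epoch == "post_cond", , drop = FALSE]
    data.frame(subject = ds$subject_id, condition = ds$condition,
               sigma_baseline = base$mean_sigma, sem_baseline = base$sem_sigma,
               n_baseline = base$n_accepted,
               sigma_post = post$mean_sigma, sem_post = post$sem_sigma,
               n_post = post$n_accepted)
  })
  subjects <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  subjects$delta_sigma <- subjects$sigma_post - subjects$sigma_baseline
  if (!is.null(behavior))
    subjects <- merge(subjects, behavior[, c("subject", "learning_score")],
                      by = "subject", sort = FALSE)
  list(subjects = subjects, groups = group_change_summary(subjects))
}
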