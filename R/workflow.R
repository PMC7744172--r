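#' Stage timings for the pipelined biopsy workflow
#'
#' Durations of each stage of the rapid 3D pathology workflow, in minutes
#' unless noted. Staining and rinsing happen simultaneously for the whole
#' batch; loading is a single batch step; imaging is strictly sequential
#' (one microscope); processing of each biopsy starts the moment its imaging
#' ends (up to `process_workers` concurrent jobs, FIFO when limited); a
#' single pathologist diagnoses datasets in order as they become ready.
#'
#' Defaults: 5 min stain, 1.5 min rinse (3 x 30 s), 3 min load (the load time
#' is this package's assumption — it is not reported anywhere, which is why
#' absolute batch turnaround is validated against a discrete-event oracle
#' rather than a published total), 2 min imaging and 8 min processing per
#' biopsy, 35 s diagnosis per biopsy, unbounded processing workers.
#'
#' @param stain_min,rinse_min,load_min Batch-level prep stages, minutes.
#' @param image_min_per_biopsy,process_min_per_biopsy Per-biopsy stage
#'   durations, minutes.
#' @param diagnose_sec_per_biopsy Per-biopsy diagnosis time, seconds.
#' @param process_workers Number of concurrent processing jobs; `Inf` for
#'   unbounded.
#' @return A list of class `stage_timing`.
#' @export
stage_timing <- function(stain_min = 5, rinse_min = 1.5, load_min = 3,
                         image_min_per_biopsy = 2,
                         process_min_per_biopsy = 8,
                         diagnose_sec_per_biopsy = 35,
                         process_workers = Inf) {
  vals <- c(stain_min, rinse_min, load_min, image_min_per_biopsy,
            process_min_per_biopsy, diagnose_sec_per_biopsy)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all stage durations must be finite and >= 0")
  if (!(is.infinite(process_workers) || process_workers >= 1))
    stop("process_workers must be >= 1 or Inf")
  structure(list(stain_min = stain_min, rinse_min = rinse_min,
                 load_min = load_min,
                 image_min_per_biopsy = image_min_per_biopsy,
                 process_min_per_biopsy = process_min_per_biopsy,
                 diagnose_sec_per_biopsy = diagnose_sec_per_biopsy,
                 process_workers = process_workers),
            class = "stage_timing")
}

#' Build the pipelined batch schedule
#'
#' Computes event times (minutes from batch start) for every biopsy in a
#' batch: the whole batch is stained, rinsed and loaded serially; biopsies
#' are then imaged back to back; each biopsy's processing starts when its
#' imaging ends (queueing FIFO if workers are limited); a single reader
#' diagnoses each dataset as soon as it is processed and the reader is free.
#'
#' @param n_biopsies Number of biopsies in the batch (>= 1); 12 is the
#'   standard prostate sampling.
#' @param timing A [stage_timing()].
#' @return An object of class `otls_schedule`: list with `events` (data.frame
#'   of per-biopsy `image_start`, `image_end`, `process_start`, `process_end`,
#'   `diagnose_start`, `diagnose_end`), `last_dataset_ready`,
#'   `total_turnaround`, `timing`, `n_biopsies`.
#' @examples
#' s <- build_schedule(12, stage_timing())
#' s$last_dataset_ready  # 9.5 + 24 + 8 = 41.5 min
#' @export
build_schedule <- function(n_biopsies, timing = stage_timing()) {
  stopifnot(inherits(timing, "stage_timing"))
  n <- as.integer(n_biopsies)
  if (is.na(n) || n < 1L) stop("n_biopsies must be >= 1")
  offset <- timing$stain_min + timing$rinse_min + timing$load_min
  ti <- timing$image_min_per_biopsy
  tp <- timing$process_min_per_biopsy
  td <- timing$diagnose_sec_per_biopsy / 60
  w <- timing$process_workers

  image_start <- offset + (seq_len(n) - 1) * ti
  image_end <- image_start + ti

  process_start <- numeric(n)
  process_end <- numeric(n)
  if (is.infinite(w)) {
    process_start <- image_end
  } else {
    w <- as.integer(w)
    free <- numeric(w)                     # next-free time per worker
    for (i in seq_len(n)) {
      j <- which.min(free)
      process_start[i] <- max(image_end[i], free[j])
      free[j] <- process_start[i] + tp
    }
  }
  process_end <- process_start + tp

  diagnose_start <- numeric(n)
  diagnose_end <- numeric(n)
  prev <- -Inf
  for (i in seq_len(n)) {
    diagnose_start[i] <- max(process_end[i], prev)
    diagnose_end[i] <- diagnose_start[i] + td
    prev <- diagnose_end[i]
  }

  events <- data.frame(biopsy = seq_len(n),
                       image_start = image_start, image_end = image_end,
                       process_start = process_start,
                       process_end = process_end,
                       diagnose_start = diagnose_start,
                       diagnose_end = diagnose_end)
  structure(list(events = events,
                 last_dataset_ready = max(process_end),
                 total_turnaround = diagnose_end[n],
                 timing = timing, n_biopsies = n),
            class = "otls_schedule")
}

#' @export
print.otls_schedule <- function(x, ...) {
  cat(sprintf("Pipelined schedule, %d biopsies\n", x$n_biopsies))
  cat(sprintf("  last dataset ready : %.2f min\n", x$last_dataset_ready))
  cat(sprintf("  total turnaround   : %.2f min\n", x$total_turnaround))
  invisible(x)
}

#' Summarise a schedule's critical path and idle time
#'
#' Decomposes the total turnaround into sequential critical-path segments —
#' batch prep (stain + rinse + load), the imaging span, the processing tail
#' after the last image, and the diagnosis tail after the last dataset — and
#' reports the reader's idle gap before each diagnosis.
#'
#' @param schedule An [build_schedule()] result.
#' @return A list of class `otls_turnaround`: `total_turnaround`,
#'   `last_dataset_ready`, `critical_path` (named numeric: `prep`, `imaging`,
#'   `processing_tail`, `diagnosis_tail`, minutes), `idle_before_diagnosis`
#'   (per-biopsy minutes the reader waits), `dominant_stage`.
#' @export
turnaround_summary <- function(schedule) {
  stopifnot(inherits(schedule, "otls_schedule"))
  ev <- schedule$events
  n <- schedule$n_biopsies
  t <- schedule$timing
  prep <- t$stain_min + t$rinse_min + t$load_min
  imaging <- ev$image_end[n] - ev$image_start[1]
  processing_tail <- schedule$last_dataset_ready - ev$image_end[n]
  diagnosis_tail <- schedule$total_turnaround - schedule$last_dataset_ready
  cp <- c(prep = prep, imaging = imaging,
          processing_tail = processing_tail,
          diagnosis_tail = diagnosis_tail)
  idle <- ev$diagnose_start - c(prep, ev$diagnose_end[-n])
  structure(list(total_turnaround = schedule$total_turnaround,
                 last_dataset_ready = schedule$last_dataset_ready,
                 critical_path = cp,
                 idle_before_diagnosis = idle,
                 dominant_stage = names(cp)[which.max(cp)]),
            class = "otls_turnaround")
}

#' @export
print.otls_turnaround <- function(x, ...) {
  cat(sprintf("Turnaround %.2f min (last dataset ready %.2f min)\n",
              x$total_turnaround, x$last_dataset_ready))
  cp <- x$critical_path
  for (nm in names(cp))
    cat(sprintf("  %-16s %6.2f min\n", nm, cp[[nm]]))
  cat(sprintf("  dominant stage: %s\n", x$dominant_stage))
  invisible(x)
}

#' Read stage timings from a YAML config
#'
#' Expects top-level keys matching the [stage_timing()] arguments; missing
#' keys take the defaults. `process_workers: unbounded` (or `.inf`) maps to
#' `Inf`.
#' @param path YAML file path.
#' @return A [stage_timing()].
#' @export
read_timing_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (identical(cfg$process_workers, "unbounded")) cfg$process_workers <- Inf
  keep <- intersect(names(cfg), names(formals(stage_timing)))
  do.call(stage_timing, cfg[keep])
}
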