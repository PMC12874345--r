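# Wall-clock and resident-memory profiling of callable units.

# Resident set size of a process in MB, from /proc (Linux) with a ps
# fallback; NA when neither is available.
.rss_mb <- function(pid = Sys.getpid()) {
  status <- sprintf("/proc/%d/status", pid)
  if (file.exists(status)) {
    ln <- grep("^VmRSS:", readLines(status, warn = FALSE), value = TRUE)
    if (length(ln)) {
      return(as.numeric(gsub("[^0-9]", "", ln[1])) / 1024)
    }
  }
  out <- suppressWarnings(
    try(system2("ps", c("-o", "rss=", "-p", pid), stdout = TRUE),
        silent = TRUE))
  if (!inherits(out, "try-error") && length(out)) {
    return(as.numeric(trimws(out[1])) / 1024)
  }
  NA_real_
}

#' Profile a task's wall time and resident memory
#'
#' Runs \code{task} \code{repetitions} times, recording the wall-clock time
#' of each run, while a forked sampler process records the resident set size
#' of this R process on a periodic cadence. Peak memory is the maximum
#' sample, mean and sd are over all samples. If the task throws, profiling
#' is aborted and the error is rethrown with the partial record attached as
#' the condition field \code{record}.
#'
#' @param task A zero-argument function.
#' @param phase Label, conventionally \code{"train"} or \code{"test"}.
#' @param repetitions Number of runs (>= 1, default 1).
#' @param sampling_interval Memory sampling cadence in seconds
#'   (default 0.05).
#' @return Object of class \code{profiling_record}: \code{phase},
#'   \code{wall_s} (mean), \code{wall_sd_s}, \code{wall_times_s},
#'   \code{mem_peak_mb}, \code{mem_mean_mb}, \code{mem_sd_mb},
#'   \code{n_samples}, \code{repetitions}, \code{value} (last task result).
#' @export
profile_execution <- function(task, phase = "train", repetitions = 1L,
                              sampling_interval = 0.05) {
  stopifnot(is.function(task), repetitions >= 1, sampling_interval > 0)
  pid <- Sys.getpid()
  sample_file <- tempfile("rss_")
  stop_file <- tempfile("stop_")
  child <- NULL
  can_fork <- .Platform$OS.type == "unix"
  samples0 <- .rss_mb(pid)                       # at least one sample
  if (can_fork) {
    child <- parallel::mcparallel({
      while (!file.exists(stop_file)) {
        cat(.rss_mb(pid), "\n", file = sample_file, append = TRUE)
        Sys.sleep(sampling_interval)
      }
      invisible(NULL)
    }, silent = TRUE)
  }
  stop_sampler <- function() {
    file.create(stop_file)
    if (!is.null(child)) {
      try(parallel::mccollect(child, wait = TRUE), silent = TRUE)
    }
  }
  times <- numeric(repetitions)
  value <- NULL
  err <- NULL
  for (r in seq_len(repetitions)) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(task(), error = function(e) {
      err <<- e
      NULL
    })
    times[r] <- proc.time()[["elapsed"]] - t0
    if (!is.null(err)) {
      times <- times[seq_len(r)]
      break
    }
  }
  stop_sampler()
  mem <- samples0
  if (file.exists(sample_file)) {
    got <- suppressWarnings(scan(sample_file, quiet = TRUE))
    mem <- c(mem, got[is.finite(got)])
  }
  mem <- c(mem, .rss_mb(pid))
  mem <- mem[is.finite(mem)]
  rec <- structure(list(
    phase = phase,
    wall_s = mean(times), wall_sd_s = stats::sd(times),
    wall_times_s = times,
    mem_peak_mb = if (length(mem)) max(mem) else NA_real_,
    mem_mean_mb = if (length(mem)) mean(mem) else NA_real_,
    mem_sd_mb = if (length(mem) > 1) stats::sd(mem) else 0,
    n_samples = length(mem), repetitions = repetitions,
    value = value), class = "profiling_record")
  if (!is.null(err)) {
    stop(errorCondition(
      paste0("task failed during profiling: ", conditionMessage(err)),
      record = rec, class = c("profiling_error", "error")))
  }
  rec
}

#' @export
print.profiling_record <- function(x, ...) {
  cat(sprintf("Profiling [%s]: wall %.3f s (sd %.3f, n = %d reps)\n",
              x$phase, x$wall_s, x$wall_sd_s, x$repetitions))
  cat(sprintf("  RSS: peak %.1f MB, mean %.1f MB (sd %.1f, %d samples)\n",
              x$mem_peak_mb, x$mem_mean_mb, x$mem_sd_mb, x$n_samples))
  invisible(x)
}
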