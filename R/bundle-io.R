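#' Write a trial bundle to a directory
#'
#' Serializes a trial bundle as one JSON manifest plus plain-text arrays:
#' `manifest.json` (sampling rates, MVC reference, unit metadata, seed),
#' `emg.tsv`, `torque.tsv`, `profile.tsv` (excitation profile), and per
#' unit `mu_<id>_firings.tsv` (one discharge time in s per line) and
#' `mu_<id>_muap.tsv`. Every number is written with 17 significant digits
#' (numbers inside the JSON manifest as strings), so the round trip
#' through [read_trial_bundle()] is floating-point exact.
#'
#' @param bundle A `trial_bundle`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_trial_bundle()]
#' @export
write_trial_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  num <- function(x) sprintf("%.17g", x)
  writeLines(num(bundle$emg), file.path(path, "emg.tsv"))
  writeLines(num(bundle$torque), file.path(path, "torque.tsv"))
  prof <- bundle$profile
  writeLines(c("time\texcitation\tsegment",
               paste(num(prof$time), num(prof$excitation), prof$segment,
                     sep = "\t")),
             file.path(path, "profile.tsv"))
  units <- bundle$units
  for (i in seq_len(nrow(units))) {
    id <- units$id[i]
    writeLines(num(units$firings[[i]]),
               file.path(path, sprintf("mu_%03d_firings.tsv", id)))
    writeLines(num(units$muap[[i]]),
               file.path(path, sprintf("mu_%03d_muap.tsv", id)))
  }
  traps <- attr(bundle$profile, "trapezoids")
  manifest <- list(
    emg_fs = num(bundle$emg_fs),
    torque_fs = num(bundle$torque_fs),
    mvc_rms = num(bundle$mvc_rms),
    duration = num(bundle$duration),
    target_mvc = num(bundle$target_mvc),
    seed = bundle$seed,
    units = lapply(seq_len(nrow(units)), function(i) {
      u <- list(id = units$id[i])
      for (f in c("rt_true", "p_true", "tr_true", "thr_true")) {
        if (f %in% names(units)) u[[f]] <- num(units[[f]][i])
      }
      if ("decomposed" %in% names(units)) u$decomposed <- units$decomposed[i]
      u
    }),
    trapezoids = if (!is.null(traps)) {
      list(trapezoid = traps$trapezoid, start = num(traps$start),
           end = num(traps$end))
    }
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trial bundle from a directory
#'
#' Inverse of [write_trial_bundle()]; `read(write(b))` reproduces every
#' numeric field exactly. A missing manifest or array file raises an error
#' naming the missing component.
#'
#' @param path Bundle directory.
#' @return A `trial_bundle`.
#' @export
read_trial_bundle <- function(path) {
  need <- function(file, what) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) {
      abort(sprintf("trial bundle at '%s' is missing its %s file ('%s')",
                    path, what, file))
    }
    fp
  }
  manifest <- jsonlite::read_json(need("manifest.json", "manifest"),
                                  simplifyVector = TRUE)
  read_num <- function(fp) {
    x <- readLines(fp)
    if (length(x) == 0) numeric(0) else as.numeric(x)
  }
  emg <- read_num(need("emg.tsv", "EMG"))
  torque <- read_num(need("torque.tsv", "torque"))
  prof_raw <- utils::read.delim(need("profile.tsv", "excitation-profile"),
                                colClasses = c("character", "character",
                                               "character"))
  profile <- tibble::tibble(
    time = as.numeric(prof_raw$time),
    excitation = as.numeric(prof_raw$excitation),
    segment = prof_raw$segment
  )
  if (!is.null(manifest$trapezoids)) {
    attr(profile, "trapezoids") <- tibble::tibble(
      trapezoid = as.integer(manifest$trapezoids$trapezoid),
      start = as.numeric(manifest$trapezoids$start),
      end = as.numeric(manifest$trapezoids$end)
    )
  }
  uinfo <- manifest$units
  n_units <- if (is.null(uinfo) || length(uinfo) == 0) 0L
             else nrow(as.data.frame(uinfo))
  if (n_units > 0) {
    uinfo <- tibble::as_tibble(uinfo)
    units <- tibble::tibble(id = as.integer(uinfo$id))
    for (f in c("rt_true", "p_true", "tr_true", "thr_true")) {
      if (f %in% names(uinfo)) units[[f]] <- as.numeric(uinfo[[f]])
    }
    units$muap <- lapply(units$id, function(id) {
      read_num(need(sprintf("mu_%03d_muap.tsv", id),
                    sprintf("unit %d MUAP-template", id)))
    })
    units$firings <- lapply(units$id, function(id) {
      read_num(need(sprintf("mu_%03d_firings.tsv", id),
                    sprintf("unit %d firing-times", id)))
    })
    if ("decomposed" %in% names(uinfo)) {
      units$decomposed <- as.logical(uinfo$decomposed)
    }
  } else {
    units <- tibble::tibble(id = integer(0), rt_true = numeric(0),
                            p_true = numeric(0), tr_true = numeric(0),
                            thr_true = numeric(0), muap = list(),
                            firings = list())
  }
  structure(list(
    units = units, emg = emg, emg_fs = as.numeric(manifest$emg_fs),
    torque = torque, torque_fs = as.numeric(manifest$torque_fs),
    mvc_rms = as.numeric(manifest$mvc_rms), profile = profile,
    duration = as.numeric(manifest$duration),
    target_mvc = as.numeric(manifest$target_mvc),
    seed = manifest$seed
  ), class = "trial_bundle")
}
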