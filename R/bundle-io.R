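#' Write / read an experiment bundle
#'
#' One directory per field of view, all plain text: `cells.csv`
#' (id,x_um,y_um,is_target), per session `F_<session>.csv` and
#' `Fneu_<session>.csv` (cell x frame matrices, no header),
#' `events_<session>.csv` (onset_s,tone_khz,stim), `truth.csv` (per-cell
#' ground truth), and `meta.yaml` (frame_rate_hz, condition, seed, session
#' order). The round trip is lossless to write precision (~15 significant
#' digits).
#'
#' @param bundle an `experiment_bundle` from [simulate_experiment()].
#' @param path directory to create/populate.
#' @return `write_bundle` returns `path` invisibly; `read_bundle` returns the
#'   reconstructed `experiment_bundle`.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(bundle$cells, file.path(path, "cells.csv"))
  data.table::fwrite(bundle$truth, file.path(path, "truth.csv"))
  for (nm in names(bundle$sessions)) {
    s <- bundle$sessions[[nm]]
    data.table::fwrite(data.table::as.data.table(s$F),
                       file.path(path, paste0("F_", nm, ".csv")),
                       col.names = FALSE)
    data.table::fwrite(data.table::as.data.table(s$Fneu),
                       file.path(path, paste0("Fneu_", nm, ".csv")),
                       col.names = FALSE)
    data.table::fwrite(s$events,
                       file.path(path, paste0("events_", nm, ".csv")))
  }
  meta <- list(frame_rate_hz = bundle$frame_rate_hz,
               condition = bundle$condition,
               seed = bundle$seed %||% NA,
               sessions = as.list(names(bundle$sessions)))
  yaml::write_yaml(meta, file.path(path, "meta.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("malformed bundle at '", path,
                               "': missing ", f)
    fp
  }
  meta <- yaml::read_yaml(need("meta.yaml"))
  for (k in c("frame_rate_hz", "condition", "sessions"))
    if (is.null(meta[[k]])) stop("malformed bundle: meta.yaml lacks '", k, "'")
  cells <- as.data.frame(data.table::fread(need("cells.csv")))
  truth <- as.data.frame(data.table::fread(need("truth.csv")))
  sessions <- lapply(meta$sessions, function(nm) {
    f <- as.matrix(data.table::fread(need(paste0("F_", nm, ".csv")),
                                     header = FALSE))
    fneu <- as.matrix(data.table::fread(need(paste0("Fneu_", nm, ".csv")),
                                        header = FALSE))
    ev <- as.data.frame(data.table::fread(need(paste0("events_", nm,
                                                      ".csv"))))
    dimnames(f) <- dimnames(fneu) <- NULL
    if (!identical(dim(f), dim(fneu)))
      stop("malformed bundle: F/Fneu shape mismatch in session ", nm)
    list(F = f, Fneu = fneu, events = ev)
  })
  names(sessions) <- unlist(meta$sessions)
  seed <- meta$seed
  if (length(seed) == 0 || is.na(seed)) seed <- NULL
  structure(list(cells = cells, sessions = sessions,
                 frame_rate_hz = meta$frame_rate_hz,
                 condition = meta$condition, truth = truth, seed = seed),
            class = "experiment_bundle")
}
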