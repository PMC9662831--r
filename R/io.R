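.traj_columns <- c("time_min", "cell_id", "plasmid_id", "x_um",
                   "cell_length_um")

#' Write trajectories as a delimited table
#'
#' One row per (timepoint, plasmid): columns \code{time_min},
#' \code{cell_id}, \code{plasmid_id}, \code{x_um} (mid-cell-relative,
#' negative towards the designated old pole), \code{cell_length_um}, and
#' \code{tether_count} where available.  A flat key-value metadata sidecar
#' (\code{<path>.meta}) records the parameter snapshot, seed, nucleoid
#' length and event counters of simulated trajectories.
#'
#' @param trajs a \code{"par_trajectory"} or a (optionally named) list of
#'   them; names become \code{cell_id}s.
#' @param path output file path.
#' @param delimiter field delimiter (default tab).
#' @param sidecar write the metadata sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_trajectory_table <- function(trajs, path, delimiter = "\t",
                                   sidecar = TRUE) {
  if (inherits(trajs, "par_trajectory")) trajs <- list(trajs)
  ids <- names(trajs)
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_along(trajs))
  rows <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    stopifnot(inherits(tr, "par_trajectory"))
    cl <- if (!is.null(tr$cell_lengths)) tr$cell_lengths
          else rep(tr$L, length(tr$times))
    do.call(rbind, lapply(seq_len(ncol(tr$positions)), function(j) {
      keep <- !is.na(tr$positions[, j])
      d <- data.frame(time_min = tr$times[keep] / 60, cell_id = ids[i],
                      plasmid_id = sprintf("p%d", j),
                      x_um = tr$positions[keep, j],
                      cell_length_um = cl[keep], stringsAsFactors = FALSE)
      if (!is.null(tr$tether_counts))
        d$tether_count <- tr$tether_counts[keep, j]
      d
    }))
  }))
  utils::write.table(rows, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  if (sidecar) {
    meta <- character(0)
    tr1 <- trajs[[1]]
    add <- function(k, v) sprintf("%s = %s", k, format(v, digits = 17))
    meta <- c(meta, add("n_trajectories", length(trajs)),
              add("L_um", tr1$L),
              add("sampling_interval_s", tr1$sampling_interval),
              add("source", tr1$source))
    if (!is.null(tr1$seed)) meta <- c(meta, add("seed", tr1$seed))
    if (!is.null(tr1$params))
      meta <- c(meta, vapply(names(unclass(tr1$params)), function(k)
        add(paste0("param_", k), tr1$params[[k]]), ""))
    if (!is.null(tr1$counters))
      meta <- c(meta, vapply(names(tr1$counters), function(k)
        add(k, tr1$counters[[k]]), ""))
    writeLines(meta, paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read trajectories from a delimited table
#'
#' Parses a tracking table (mandatory header columns \code{time_min},
#' \code{cell_id}, \code{plasmid_id}, \code{x_um}, \code{cell_length_um})
#' into one trajectory per (cell, plasmid).  Each series must have strictly
#' increasing, uniformly spaced times, and positions must satisfy
#' \code{|x_um| <= cell_length_um/2 + 0.01}; violations are reported with
#' their row numbers.
#'
#' @param path input file.
#' @param delimiter field delimiter (default tab).
#' @return Named list of \code{"par_trajectory"} objects
#'   (\code{"<cell_id>/<plasmid_id>"}).
#' @export
read_trajectories <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(.traj_columns, names(tab))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("time_min", "x_um", "cell_length_um")) {
    if (!is.numeric(tab[[col]]))
      stop("column '", col, "' contains non-numeric values (e.g. row ",
           which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1], ")")
  }
  bad <- which(abs(tab$x_um) > tab$cell_length_um / 2 + 0.01)
  if (length(bad))
    stop("position outside the cell at data row ", bad[1],
         ": |x_um| = ", abs(tab$x_um[bad[1]]), " > cell_length_um/2 + 0.01")
  key <- interaction(tab$cell_id, tab$plasmid_id, drop = TRUE, sep = "/")
  out <- lapply(split(tab, key), function(d) {
    d <- d[order(d$time_min), ]
    dt <- diff(d$time_min)
    if (any(dt <= 0))
      stop("non-increasing times for trajectory ", d$cell_id[1], "/",
           d$plasmid_id[1])
    if (length(dt) > 1 && diff(range(dt)) > 1e-6 * max(dt))
      stop("non-uniform sampling for trajectory ", d$cell_id[1], "/",
           d$plasmid_id[1])
    tr <- new_trajectory(times = d$time_min * 60,
                         positions = matrix(d$x_um, ncol = 1),
                         L = max(d$cell_length_um),
                         sampling_interval = if (length(dt)) dt[1] * 60 else NA,
                         seed = NA, cell_lengths = d$cell_length_um,
                         source = "file",
                         ids = c(cell = d$cell_id[1],
                                 plasmid = d$plasmid_id[1]))
    if ("tether_count" %in% names(d))
      tr$tether_counts <- matrix(d$tether_count, ncol = 1)
    tr
  })
  out[order(names(out))]
}
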