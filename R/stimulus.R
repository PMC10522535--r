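# Travelling-wave stimulus construction.
#
# A stimulus sequence is a time-points x sites binary matrix: entry (t, s) = 1
# when site s is ON during volume t. The three paradigms sweep "lines" of the
# grid in succession, each line ON for s_on seconds:
#   between  - 4 digit columns (all PD sites of one digit at once)
#   within   - 4 PD rows (the same PD site on all four digits at once)
#   diagonal - the 7 anti-diagonals of the 4x4 grid, ordered from the
#              (D2, PD1) corner, i.e. line k = sites with digit + pd - 1 = k
# Forward runs ascend through the lines; a reverse run is the time-reversed
# forward run.

#' Lines of stimulation for one paradigm
#'
#' @param paradigm One of `"between"`, `"within"`, `"diagonal"`.
#' @param grid A [grid_spec()].
#' @return A list of integer vectors, each the linear site indices
#'   stimulated simultaneously in one line, in forward sweep order.
#' @export
stim_lines <- function(paradigm = c("between", "within", "diagonal"),
                       grid = grid_spec()) {
  paradigm <- match.arg(paradigm)
  s <- grid$sites
  switch(paradigm,
    between = lapply(seq_len(grid$n_digits), function(d) s$site[s$digit == d]),
    within = lapply(seq_len(grid$n_pd), function(p) s$site[s$pd == p]),
    diagonal = {
      n_lines <- grid$n_digits + grid$n_pd - 1L
      lapply(seq_len(n_lines), function(k) s$site[s$digit + s$pd - 1L == k])
    }
  )
}

new_stim_sequence <- function(mat, tr, cycle_len, n_cycles, paradigm,
                              direction, runs = NULL) {
  if (is.null(runs)) {
    runs <- data.frame(start = 1L, end = nrow(mat),
                       paradigm = paradigm, direction = direction,
                       cycle_len = cycle_len,
                       stringsAsFactors = FALSE)
  }
  structure(
    list(matrix = mat, tr = tr, cycle_len = cycle_len, n_cycles = n_cycles,
         paradigm = paradigm, direction = direction, runs = runs),
    class = "stim_sequence"
  )
}

#' Build a travelling-wave stimulus sequence
#'
#' Constructs the binary time-points x sites stimulus description for one run
#' of the vibrotactile travelling-wave protocol: each stimulation line is ON
#' for `s_on` seconds and the full sweep of lines repeats for `n_cycles`
#' cycles. With the default timing (4 s ON, TR 2 s, 12 cycles) a
#' between/within run spans 96 volumes (16 s cycles) and a diagonal run 168
#' volumes (28 s cycles).
#'
#' @param paradigm `"between"`, `"within"` or `"diagonal"`.
#' @param direction `"forward"` (lines ascend) or `"reverse"`
#'   (time-reversed forward sweep).
#' @param n_cycles Number of stimulation cycles (default 12).
#' @param s_on Seconds each line stays ON (default 4); must be a multiple of
#'   `tr`.
#' @param tr Repetition time in seconds (default 2).
#' @param grid A [grid_spec()].
#'
#' @return A `stim_sequence`: list with the binary `matrix`
#'   (`n_cycles * cycle_len / tr` rows), `tr`, `cycle_len` (seconds),
#'   `n_cycles`, `paradigm`, `direction`, and a `runs` table of run
#'   boundaries (one row here; grows under [concatenate_sequences()]).
#' @export
#' @examples
#' bd <- build_tw_sequence("between", "forward")
#' nrow(bd$matrix)   # 96
#' dg <- build_tw_sequence("diagonal", "forward")
#' nrow(dg$matrix)   # 168
build_tw_sequence <- function(paradigm = c("between", "within", "diagonal"),
                              direction = c("forward", "reverse"),
                              n_cycles = 12L, s_on = 4, tr = 2,
                              grid = grid_spec()) {
  paradigm <- match.arg(paradigm)
  direction <- match.arg(direction)
  stopifnot(n_cycles >= 1, s_on > 0, tr > 0)
  if (abs(s_on / tr - round(s_on / tr)) > 1e-9) {
    stop("timing granularity: s_on (", s_on,
         " s) must be a whole multiple of tr (", tr, " s)")
  }
  lines <- stim_lines(paradigm, grid)
  tp_per_line <- as.integer(round(s_on / tr))
  cycle_len <- length(lines) * s_on
  cycle_tp <- length(lines) * tp_per_line

  cyc <- matrix(0, nrow = cycle_tp, ncol = grid$n_sites)
  for (k in seq_along(lines)) {
    rows <- (k - 1L) * tp_per_line + seq_len(tp_per_line)
    cyc[rows, lines[[k]]] <- 1
  }
  mat <- cyc[rep(seq_len(cycle_tp), times = n_cycles), , drop = FALSE]
  seq_out <- new_stim_sequence(mat, tr, cycle_len, n_cycles, paradigm,
                               direction)
  if (direction == "reverse") seq_out <- time_reverse_rows(seq_out)
  seq_out
}

# Reverse row order without touching the direction label.
time_reverse_rows <- function(seq) {
  seq$matrix <- seq$matrix[rev(seq_len(nrow(seq$matrix))), , drop = FALSE]
  seq
}

#' Time-reverse a stimulus sequence
#'
#' Flips the row (time) order of the stimulus matrix and toggles the
#' direction label. An involution: reversing twice restores the input.
#'
#' @param seq A `stim_sequence`.
#' @return The reversed `stim_sequence`.
#' @export
time_reverse <- function(seq) {
  stopifnot(inherits(seq, "stim_sequence"))
  out <- time_reverse_rows(seq)
  flip <- c(forward = "reverse", reverse = "forward")
  if (out$direction %in% names(flip)) {
    out$direction <- unname(flip[out$direction])
  }
  n <- nrow(seq$matrix)
  runs <- seq$runs
  new_start <- n - runs$end + 1L
  new_end <- n - runs$start + 1L
  runs$start <- new_start
  runs$end <- new_end
  runs$direction <- ifelse(runs$direction %in% names(flip),
                           unname(flip[runs$direction]), runs$direction)
  out$runs <- runs[rev(seq_len(nrow(runs))), , drop = FALSE]
  rownames(out$runs) <- NULL
  out
}

#' Concatenate stimulus sequences into one session
#'
#' Appends runs in time while recording run boundaries, so that downstream
#' HRF convolution and detrending can be carried out run-wise and never
#' cross a scan discontinuity.
#'
#' @param seqs A list of `stim_sequence` objects sharing `tr` and grid size.
#' @return A single `stim_sequence` whose `runs` table has one row per input
#'   run; `paradigm`/`direction` are `"mixed"` when inputs differ.
#' @export
concatenate_sequences <- function(seqs) {
  stopifnot(length(seqs) >= 1, all(vapply(seqs, inherits, TRUE,
                                          "stim_sequence")))
  if (length(seqs) == 1L) return(seqs[[1L]])
  trs <- vapply(seqs, function(s) s$tr, numeric(1))
  if (length(unique(trs)) != 1L) stop("mismatched tr across sequences")
  ncols <- vapply(seqs, function(s) ncol(s$matrix), integer(1))
  if (length(unique(ncols)) != 1L) stop("mismatched grid across sequences")

  mat <- do.call(rbind, lapply(seqs, function(s) s$matrix))
  offs <- cumsum(c(0L, vapply(seqs, function(s) nrow(s$matrix),
                              integer(1))))
  runs <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    r <- seqs[[i]]$runs
    r$start <- r$start + offs[i]
    r$end <- r$end + offs[i]
    r
  }))
  rownames(runs) <- NULL
  paradigms <- unique(vapply(seqs, function(s) s$paradigm, character(1)))
  dirs <- unique(vapply(seqs, function(s) s$direction, character(1)))
  new_stim_sequence(
    mat, trs[1],
    cycle_len = if (length(paradigms) == 1L) seqs[[1L]]$cycle_len else NA_real_,
    n_cycles = NA_integer_,
    paradigm = if (length(paradigms) == 1L) paradigms else "mixed",
    direction = if (length(dirs) == 1L) dirs else "mixed",
    runs = runs
  )
}

#' Write / read a stimulus sequence as TSV
#'
#' The on-disk format is a tab-separated binary matrix (rows = time-points,
#' one column per site) preceded by `#`-commented header lines carrying the
#' timing metadata.
#'
#' @param seq A `stim_sequence`.
#' @param path File path.
#' @return `write_stim_tsv` returns `path` invisibly; `read_stim_tsv`
#'   returns the reconstructed `stim_sequence`.
#' @export
write_stim_tsv <- function(seq, path) {
  stopifnot(inherits(seq, "stim_sequence"))
  hdr <- c(
    sprintf("# tr=%g", seq$tr),
    sprintf("# cycle_len=%g", seq$cycle_len),
    sprintf("# n_cycles=%d", as.integer(seq$n_cycles)),
    sprintf("# paradigm=%s", seq$paradigm),
    sprintf("# direction=%s", seq$direction),
    sprintf("# runs=%s", paste(sprintf("%d:%d:%s:%s:%g", seq$runs$start,
                                       seq$runs$end, seq$runs$paradigm,
                                       seq$runs$direction,
                                       seq$runs$cycle_len), collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(seq$matrix, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_stim_tsv
#' @export
read_stim_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s=", key), "",
                           grep(sprintf("^# %s=", key), hdr, value = TRUE))
  mat <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)],
                                     sep = "\t"))
  dimnames(mat) <- NULL
  runs_raw <- strsplit(strsplit(get("runs"), ",")[[1]], ":")
  runs <- data.frame(
    start = as.integer(vapply(runs_raw, `[`, "", 1L)),
    end = as.integer(vapply(runs_raw, `[`, "", 2L)),
    paradigm = vapply(runs_raw, `[`, "", 3L),
    direction = vapply(runs_raw, `[`, "", 4L),
    cycle_len = as.numeric(vapply(runs_raw, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
  # cycle_len / n_cycles are "NA" for mixed concatenated sessions
  new_stim_sequence(mat, tr = as.numeric(get("tr")),
                    cycle_len = suppressWarnings(
                      as.numeric(get("cycle_len"))),
                    n_cycles = suppressWarnings(
                      as.integer(get("n_cycles"))),
                    paradigm = get("paradigm"), direction = get("direction"),
                    runs = runs)
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat(sprintf(
    "<stim_sequence> %s/%s: %d volumes x %d sites, tr=%g s, %d run(s)\n",
    x$paradigm, x$direction, nrow(x$matrix), ncol(x$matrix), x$tr,
    nrow(x$runs)))
  invisible(x)
}
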