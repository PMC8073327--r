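#' Read a binary time series file
#'
#' Two plain-text dialects are auto-detected:
#' \itemize{
#'   \item a single line of `0`/`1` characters (the dense form), or
#'   \item a header line `L=<length>` followed by one signal time per line
#'     (the sparse form).
#' }
#'
#' @param path Path to the series file.
#' @return A [bls_series].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("cannot open series file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty series file: ", path)
  first <- trimws(lines[1L])
  if (grepl("^L=[0-9]+$", first)) {
    L <- as.integer(sub("^L=", "", first))
    times <- integer(0)
    if (length(lines) > 1L) {
      body <- trimws(lines[-1L])
      bad <- which(!grepl("^[0-9]+$", body))
      if (length(bad))
        stop(sprintf("malformed signal time at line %d of %s: '%s'",
                     bad[1L] + 1L, path, body[bad[1L]]))
      times <- as.integer(body)
    }
    bls_series(L, times)
  } else {
    if (length(lines) > 1L)
      stop("0/1 dialect must be a single line (line 2 of ", path,
           " is unexpected)")
    if (!grepl("^[01]+$", first))
      stop("invalid symbol in 0/1 series at line 1 of ", path)
    bits <- as.integer(strsplit(first, "")[[1L]])
    bls_series(length(bits), which(bits == 1L))
  }
}

#' Write a binary time series file
#'
#' @param series A [bls_series].
#' @param path Output path.
#' @param format `"bits"` (single 0/1 line, default) or `"times"` (header
#'   `L=<length>` plus one signal time per line).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, format = c("bits", "times")) {
  stopifnot(inherits(series, "bls_series"))
  format <- match.arg(format)
  if (format == "bits") {
    writeLines(paste(as_binary_vector(series), collapse = ""), path)
  } else {
    writeLines(c(sprintf("L=%d", series$length),
                 format(series$times, scientific = FALSE, trim = TRUE)),
               path)
  }
  invisible(path)
}

#' Write an entropy profile as a tab-separated table
#'
#' Columns `index`, `time`, `entropy` (12 decimals), preceded by a comment
#' line recording the source series length so the profile round-trips.
#'
#' @param profile A non-empty [bls_profile].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "bls_profile"))
  if (length(profile$values) == 0L) stop("cannot write an empty profile")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source_length=%d", profile$source_length), con)
  writeLines("index\ttime\tentropy", con)
  writeLines(sprintf("%d\t%d\t%.12f", seq_along(profile$times),
                     profile$times, profile$values), con)
  invisible(path)
}

#' Read an entropy profile table written by [write_profile]
#'
#' @param path Path to the tab-separated profile file.
#' @return A [bls_profile].
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  src <- grep("^# source_length=[0-9]+$", lines, value = TRUE)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  need <- c("index", "time", "entropy")
  if (!all(need %in% names(tab)))
    stop("profile file missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  L <- if (length(src)) as.integer(sub("^# source_length=", "", src[1L]))
       else max(tab$time)
  bls_profile(tab$time, tab$entropy, L)
}

#' Read a trajectory from CSV
#'
#' Expects columns `x` and `y`; any other columns (e.g. a frame time `t`)
#' are ignored.
#'
#' @param path Path to the CSV file.
#' @return A [bls_trajectory].
#' @export
read_trajectory <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(tab)))
    stop("trajectory CSV must have columns 'x' and 'y'")
  bls_trajectory(tab$x, tab$y)
}

#' Write a trajectory to CSV
#'
#' @param traj A [bls_trajectory].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "bls_trajectory"))
  utils::write.csv(data.frame(x = traj$x, y = traj$y), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
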