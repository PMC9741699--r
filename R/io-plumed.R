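#' Hills records (deposited metadynamics bias)
#'
#' An ordered table of deposited Gaussians: time (ps), centre (nm), width
#' sigma (nm) and height (kJ/mol). Times must be strictly increasing,
#' widths positive and heights non-negative.
#'
#' @param time,center,sigma,height numeric vectors of equal length
#' @param cv_name label of the collective variable
#' @return data.frame of class `hills_record`
#' @export
hills_record <- function(time = numeric(), center = numeric(),
                         sigma = numeric(), height = numeric(),
                         cv_name = "com_distance") {
  n <- length(time)
  stopifnot(length(center) == n, length(sigma) == n, length(height) == n)
  if (n > 1 && any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1] + 1
    stop(sprintf("format error: non-increasing time at event %d", bad))
  }
  if (any(sigma <= 0)) stop("format error: sigma must be positive")
  if (any(height < 0)) stop("format error: height must be non-negative")
  out <- data.frame(time = time, center = center, sigma = sigma,
                    height = height)
  attr(out, "cv_name") <- cv_name
  class(out) <- c("hills_record", "data.frame")
  out
}

#' Read a PLUMED-style HILLS file
#'
#' Whitespace-delimited columns (time, centre, sigma, height); lines starting
#' with `#` are skipped. Errors cite the offending data line.
#'
#' @param path file path
#' @return a [hills_record()]
#' @export
read_hills <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  if (!any(keep)) return(hills_record())
  tb <- read.table(text = raw[keep])
  if (ncol(tb) < 4) stop("format error: expected >= 4 columns")
  time <- tb[[1]]; center <- tb[[2]]; sigma <- tb[[3]]; height <- tb[[4]]
  if (any(diff(time) <= 0)) {
    bad <- which(keep)[which(diff(time) <= 0)[1] + 1]
    stop(sprintf("format error: non-increasing time at line %d", bad))
  }
  if (any(sigma <= 0)) {
    bad <- which(keep)[which(sigma <= 0)[1]]
    stop(sprintf("format error: non-positive sigma at line %d", bad))
  }
  hills_record(time, center, sigma, height)
}

#' Write a HILLS file
#' @param hills a [hills_record()]
#' @param path file path
#' @export
write_hills <- function(hills, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time center sigma height", con)
  if (nrow(hills))
    writeLines(sprintf("%.10g %.10g %.10g %.10g", hills$time, hills$center,
                       hills$sigma, hills$height), con)
  invisible(path)
}

#' Read a COLVAR-style CV time series
#'
#' Two whitespace-delimited columns (time, cv); `#` comment lines skipped.
#'
#' @param path file path
#' @return a `cv_series` data.frame (time ps, cv nm)
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  tb <- read.table(text = raw[keep])
  out <- data.frame(time = tb[[1]], cv = tb[[2]])
  class(out) <- c("cv_series", "data.frame")
  out
}

#' Write a COLVAR file
#' @param cv a `cv_series` data.frame
#' @param path file path
#' @export
write_colvar <- function(cv, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv", con)
  writeLines(sprintf("%.10g %.10g", cv$time, cv$cv), con)
  invisible(path)
}
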