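#' Genetic map
#'
#' Cumulative genetic positions (cM) at increasing physical positions (bp),
#' used for per-window recombination rates by linear interpolation.
#'
#' @param pos physical positions in bp, strictly increasing.
#' @param cM cumulative genetic positions, non-decreasing.
#' @param sex one of `"female"`, `"male"`, `"sexavg"`.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(pos, cM, sex = "sexavg") {
  sex <- match.arg(sex, c("female", "male", "sexavg"))
  if (length(pos) != length(cM)) stop("pos and cM lengths differ")
  if (length(pos) > 1L) {
    if (any(diff(pos) <= 0)) {
      row <- which(diff(pos) <= 0)[1L] + 1L
      stop(sprintf("map positions not strictly increasing at row %d", row))
    }
    if (any(diff(cM) < 0)) {
      row <- which(diff(cM) < 0)[1L] + 1L
      stop(sprintf("decreasing cumulative cM at row %d", row))
    }
  }
  structure(list(pos = as.numeric(pos), cM = as.numeric(cM), sex = sex),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map (%s): %d points, %.0f bp, %.2f cM\n", x$sex,
              length(x$pos), diff(range(x$pos)),
              if (length(x$cM)) max(x$cM) - min(x$cM) else 0))
  invisible(x)
}

#' Read a genetic map from a two-column TSV (position bp, cumulative cM)
#'
#' A header line is detected and skipped when the first field is non-numeric.
#'
#' @param path path to the TSV.
#' @param sex map variant label, one of `"female"`, `"male"`, `"sexavg"`.
#' @return A [genetic_map].
#' @export
read_genetic_map <- function(path, sex = "sexavg") {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t| +")[[1L]][1L])))
  tab <- utils::read.table(path, header = has_header, sep = "\t")
  genetic_map(tab[[1L]], tab[[2L]], sex = sex)
}

#' Cumulative genetic position at physical positions
#'
#' Linear interpolation between flanking map points; positions outside the
#' map range clamp to the terminal cM values.
#'
#' @param map a [genetic_map].
#' @param pos physical positions (bp).
#' @return Cumulative cM at each position.
#' @export
interpolate_cM <- function(map, pos) {
  if (length(map$pos) == 0L) return(rep(0, length(pos)))
  if (length(map$pos) == 1L) return(rep(map$cM, length(pos)))
  stats::approx(map$pos, map$cM, xout = pos, rule = 2)$y
}
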