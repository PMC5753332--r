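#' Window statistic rows
#'
#' The unit exported to browser tracks: one window x one population x one
#' statistic. Constructed as a plain data.frame with columns `chrom`,
#' `start`, `end` (0-based half-open), `population`, `statistic`, `value`.
#'
#' @param chrom,start,end window coordinates (0-based half-open).
#' @param population population label.
#' @param statistic track-vocabulary statistic name (e.g. `"Pi"`,
#'   `"Tajima_D"`, `"Kelly_ZnS"`, `"iHS"`).
#' @param value numeric value, `NA` when undefined.
#' @return A data.frame of window statistic rows.
#' @export
window_stats_row <- function(chrom, start, end, population, statistic, value) {
  data.frame(chrom = chrom, start = start, end = end,
             population = population, statistic = statistic, value = value,
             stringsAsFactors = FALSE)
}

#' Write window statistic rows as a browser track
#'
#' All rows must share one statistic (and one population); mixing statistics
#' in one track is an error. bedGraph uses 0-based half-open coordinates and
#' omits missing values; GFF3 uses 1-based inclusive coordinates; TSV writes
#' missing values as `"."`. Values are written at full double precision so a
#' bedGraph round-trip is exact.
#'
#' @param rows data.frame of window statistic rows ([window_stats_row]).
#' @param format one of `"bedGraph"`, `"GFF3"`, `"TSV"`.
#' @param path output file path.
#' @return Invisibly, the output path.
#' @export
write_track <- function(rows, format = c("bedGraph", "GFF3", "TSV"), path) {
  format <- match.arg(format)
  stats_seen <- unique(rows$statistic)
  if (length(stats_seen) > 1L)
    stop("mixed statistics in one track: ", paste(stats_seen, collapse = ", "))
  if (length(unique(rows$population)) > 1L)
    stop("mixed populations in one track")
  fmt <- function(v) sprintf("%.17g", v)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "bedGraph") {
    keep <- !is.na(rows$value)
    writeLines(sprintf("track type=bedGraph name=%s_%s",
                       stats_seen, unique(rows$population)), con)
    if (any(keep))
      writeLines(paste(rows$chrom[keep], rows$start[keep], rows$end[keep],
                       fmt(rows$value[keep]), sep = "\t"), con)
  } else if (format == "GFF3") {
    writeLines("##gff-version 3", con)
    keep <- !is.na(rows$value)
    if (any(keep))
      writeLines(paste(rows$chrom[keep], "popgenwin", stats_seen,
                       rows$start[keep] + 1, rows$end[keep],
                       fmt(rows$value[keep]), ".", ".",
                       sprintf("population=%s", rows$population[keep]),
                       sep = "\t"), con)
  } else {
    writeLines(paste("chrom", "start", "end", "population", "statistic",
                     "value", sep = "\t"), con)
    val <- ifelse(is.na(rows$value), ".", fmt(rows$value))
    writeLines(paste(rows$chrom, rows$start, rows$end, rows$population,
                     rows$statistic, val, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph track back into window statistic rows
#'
#' Inverse of [write_track] for the bedGraph format (used for round-trip
#' checks and downstream re-import).
#'
#' @param path bedGraph file path.
#' @param population,statistic labels to attach (bedGraph itself stores
#'   neither; defaults parse the track name line when present).
#' @return A data.frame of window statistic rows.
#' @export
read_bedgraph <- function(path, population = NA_character_,
                          statistic = NA_character_) {
  lines <- readLines(path)
  hdr <- grepl("^(track|#|browser)", lines)
  if (any(hdr) && is.na(statistic)) {
    nm <- sub("^track type=bedGraph name=", "", lines[hdr][1L])
    parts <- strsplit(nm, "_(?=[^_]+$)", perl = TRUE)[[1L]]
    if (length(parts) == 2L) { statistic <- parts[1L]; population <- parts[2L] }
  }
  lines <- lines[!hdr & nzchar(lines)]
  if (length(lines) == 0L)
    return(window_stats_row(character(0), numeric(0), numeric(0),
                            character(0), character(0), numeric(0)))
  f <- strsplit(lines, "\t")
  window_stats_row(chrom = vapply(f, `[`, "", 1L),
                   start = as.numeric(vapply(f, `[`, "", 2L)),
                   end = as.numeric(vapply(f, `[`, "", 3L)),
                   population = population, statistic = statistic,
                   value = as.numeric(vapply(f, `[`, "", 4L)))
}
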