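# FASTA input/output and annotation serialization.

#' Read satellite arrays from FASTA
#'
#' Each record becomes one array. Sequences are uppercased, `U` is mapped
#' to `T`, and any symbol outside `{A,C,G,T,N}` is mapped to `N` with a
#' warning (shotgun contigs often contain IUPAC ambiguity codes).
#'
#' @param path path to a FASTA file.
#' @return A list of `sat_array` objects (`id`, `sequence`, `orientation`),
#'   empty for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) return(list())
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA header at line ", nonblank[1],
         ": expected '>' record start")
  recs <- Biostrings::readBStringSet(path)
  out <- vector("list", length(recs))
  ids <- sub("\\s.*$", "", names(recs))
  for (i in seq_along(recs)) {
    s <- toupper(as.character(recs[[i]]))
    s <- chartr("U", "T", s)
    bad <- gsub("[ACGTN]", "", s)
    if (nchar(bad) > 0) {
      warning("array '", ids[i], "': ", nchar(bad),
              " non-ACGTN symbol(s) mapped to N")
      s <- gsub("[^ACGTN]", "N", s)
    }
    out[[i]] <- sat_array(ids[i], s)
  }
  out
}

#' Construct a satellite array object
#'
#' @param id array identifier.
#' @param sequence uppercase DNA over `{A,C,G,T,N}`.
#' @param orientation `"forward"`, `"reverse-complemented"` or `"unknown"`.
#' @return An object of class `sat_array`.
#' @export
sat_array <- function(id, sequence,
                      orientation = c("unknown", "forward",
                                      "reverse-complemented")) {
  orientation <- match.arg(orientation)
  if (!nzchar(sequence)) stop("empty sequence for array ", id)
  if (grepl("[^ACGTN]", sequence))
    stop("array ", id, ": sequence contains symbols outside {A,C,G,T,N}")
  structure(list(id = id, sequence = sequence, orientation = orientation),
            class = "sat_array")
}

.array_seq <- function(x) {
  if (inherits(x, "sat_array")) x$sequence else as.character(x)
}
.array_id <- function(x, default = "array") {
  if (inherits(x, "sat_array")) x$id else default
}

#' Write satellite arrays (or any named sequences) to FASTA
#'
#' @param x a list of `sat_array` objects or a named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.list(x) && length(x) && inherits(x[[1]], "sat_array")) {
    seqs <- vapply(x, `[[`, character(1), "sequence")
    names(seqs) <- vapply(x, `[[`, character(1), "id")
  } else seqs <- x
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Annotation records
#'
#' A flat table of interval annotations on arrays, using 0-based half-open
#' coordinates internally (BED convention); the GFF3 writer converts to
#' 1-based closed coordinates at serialization.
#'
#' @param array_id,start,end,label,score,strand vectors recycled to a
#'   common length; `start`/`end` are 0-based half-open.
#' @return A data frame of class `annotation_records`.
#' @export
annotation_records <- function(array_id, start, end, label,
                               score = 0, strand = "+") {
  n <- length(array_id)
  out <- data.frame(array_id = array_id, start = as.integer(start),
                    end = as.integer(end), label = label,
                    score = rep_len(as.numeric(score), n),
                    strand = rep_len(as.character(strand), n),
                    stringsAsFactors = FALSE)
  if (any(out$end < out$start)) stop("end < start in annotation records")
  if (!all(out$strand %in% c("+", "-", "."))) stop("invalid strand")
  class(out) <- c("annotation_records", "data.frame")
  out
}

.fmt_score <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         sub("0+$", "", sprintf("%.6f", x)))
}

#' Write annotation records to BED6, GFF3 or TSV
#'
#' BED is written 0-based half-open, GFF3 1-based closed; converting
#' between the two formats through [read_annotations()] is lossless.
#'
#' @param records an [annotation_records()] data frame.
#' @param path output file.
#' @param format `"BED"`, `"GFF3"` or `"TSV"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path, format = c("BED", "GFF3", "TSV")) {
  format <- match.arg(format)
  r <- as.data.frame(records)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "BED") {
    if (nrow(r))
      writeLines(paste(r$array_id, r$start, r$end, r$label,
                       .fmt_score(r$score), r$strand, sep = "\t"), con)
  } else if (format == "GFF3") {
    writeLines("##gff-version 3", con)
    if (nrow(r))
      writeLines(paste(r$array_id, "alphoidr", r$label,
                       r$start + 1L, r$end, .fmt_score(r$score),
                       r$strand, ".", ".", sep = "\t"), con)
  } else {
    writeLines("array_id\tstart\tend\tlabel\tscore\tstrand", con)
    if (nrow(r))
      writeLines(paste(r$array_id, r$start, r$end, r$label,
                       .fmt_score(r$score), r$strand, sep = "\t"), con)
  }
  invisible(path)
}

#' Read annotation records written by [write_annotations()]
#'
#' @param path input file.
#' @param format `"BED"`, `"GFF3"` or `"TSV"`.
#' @return An [annotation_records()] data frame (0-based half-open).
#' @export
read_annotations <- function(path, format = c("BED", "GFF3", "TSV")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "GFF3") {
    if (length(lines) == 0 || lines[1] != "##gff-version 3")
      stop("missing GFF3 version pragma")
    lines <- lines[!startsWith(lines, "#")]
  } else if (format == "TSV") {
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(annotation_records(character(0), integer(0), integer(0),
                              character(0), numeric(0), character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  if (format == "GFF3") {
    annotation_records(get(1), as.integer(get(4)) - 1L, as.integer(get(5)),
                       get(3), as.numeric(get(6)), get(7))
  } else {
    annotation_records(get(1), as.integer(get(2)), as.integer(get(3)),
                       get(4), as.numeric(get(5)), get(6))
  }
}

#' Convert a monomer table to annotation records
#'
#' @param monomers a monomer table from [segment_monomers()].
#' @param label_from column to use as feature label (default the monomer
#'   index with a `partial` suffix for clipped flanks).
#' @return An [annotation_records()] data frame.
#' @export
monomers_as_annotations <- function(monomers, label_from = NULL) {
  lab <- if (!is.null(label_from)) as.character(monomers[[label_from]])
         else paste0("monomer_", monomers$index,
                     ifelse(monomers$partial, "_partial", ""))
  annotation_records(monomers$array_id, monomers$start, monomers$end,
                     lab, score = 0, strand = "+")
}
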