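#' Read sequences from a FASTA file
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet}; plain or gzipped
#' FASTA. Record ids are truncated at the first whitespace so they match
#' manifest ids byte-for-byte.
#'
#' @param path Path to a FASTA file.
#' @return A \code{DNAStringSet}.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

.parse_spans <- function(s) {
  if (is.null(s) || length(s) == 0L || is.na(s) || !nzchar(s)) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed interval string: '", s, "'", call. = FALSE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("start", "end")))
  if (anyNA(m)) stop("malformed interval string: '", s, "'", call. = FALSE)
  m
}

.format_spans <- function(m) {
  if (nrow(m) == 0L) return("")
  paste(m[, 1L], m[, 2L], sep = "-", collapse = ";")
}

#' Read a coding-region manifest
#'
#' The manifest is a TSV with columns \code{record_id}, \code{group},
#' \code{intervals} (1-based inclusive forward-strand spans,
#' \code{"start-end"} joined by \code{";"}), and optional \code{exclusions}
#' (same syntax, e.g. the RRE span removed from \emph{env}) and \code{genes}
#' (one name per interval, \code{";"}-joined). Group labels are free text.
#'
#' @param path Path to the manifest TSV.
#' @return A data.frame with one row per record; \code{intervals} and
#'   \code{exclusions} are list-columns of two-column integer matrices,
#'   \code{genes} a list-column of character vectors (or \code{NULL}).
#' @export
read_region_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  need <- c("record_id", "group", "intervals")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$record_id)) {
    stop("duplicated record_id in manifest", call. = FALSE)
  }
  out <- data.frame(record_id = df$record_id, group = df$group,
                    stringsAsFactors = FALSE)
  out$intervals <- lapply(df$intervals, .parse_spans)
  out$exclusions <- if ("exclusions" %in% names(df)) {
    lapply(df$exclusions, .parse_spans)
  } else {
    rep(list(.parse_spans("")), nrow(df))
  }
  out$genes <- if ("genes" %in% names(df)) {
    lapply(seq_len(nrow(df)), function(i) {
      g <- df$genes[i]
      if (is.na(g) || !nzchar(g)) NULL
      else strsplit(g, ";", fixed = TRUE)[[1L]]
    })
  } else {
    rep(list(NULL), nrow(df))
  }
  for (i in seq_len(nrow(out))) {
    .validate_entry(out$intervals[[i]], out$genes[[i]], out$record_id[i])
  }
  out
}

.validate_entry <- function(intervals, genes, id) {
  if (nrow(intervals) == 0L) {
    stop("entry '", id, "' has no intervals", call. = FALSE)
  }
  if (any(intervals[, 1L] > intervals[, 2L]) || any(intervals[, 1L] < 1L)) {
    stop("entry '", id, "' has an invalid interval", call. = FALSE)
  }
  o <- order(intervals[, 1L])
  s <- intervals[o, , drop = FALSE]
  if (nrow(s) > 1L && any(s[-1L, 1L] <= s[-nrow(s), 2L])) {
    stop("entry '", id, "' has overlapping intervals", call. = FALSE)
  }
  if (!is.null(genes) && length(genes) != nrow(intervals)) {
    stop("entry '", id, "': 'genes' must name each interval", call. = FALSE)
  }
  invisible(TRUE)
}

#' Extract and validate a coding region from a genome
#'
#' Cuts the listed intervals (1-based inclusive; converted internally to
#' 0-based half-open arithmetic) from the forward strand, subtracts any
#' exclusion spans (clipped to each interval), and concatenates the remainder
#' in genomic order. Each interval is treated as one gene piece and validated
#' separately with \code{\link{count_codons}} under the strict stop policy,
#' so a terminal stop of an upstream gene is never misread as an internal
#' stop of the concatenation; a single terminal stop per piece is stripped
#' from the usage statistics.
#'
#' @param genome A single DNA string (or \code{DNAString}).
#' @param intervals Two-column matrix of (start, end) pairs, or an
#'   \code{"start-end;start-end"} string.
#' @param exclusions Optional spans removed from the intervals, same formats.
#' @param genes Optional character vector naming each interval.
#' @param id Optional record label.
#' @return An object of class \code{"coding_region"}: list with
#'   \code{pieces} (named character vector of per-interval coding sequences
#'   after exclusion subtraction), \code{sequence} (their concatenation),
#'   \code{counts} (pooled \code{"codon_counts"}), \code{piece_counts}
#'   (per-piece list), \code{record_id}.
#' @examples
#' r <- extract_regions("ATGGCTTAA", "1-9")
#' r$counts$counts[c("ATG", "GCT")]
#' @export
extract_regions <- function(genome, intervals, exclusions = NULL,
                            genes = NULL, id = NULL) {
  g <- toupper(as.character(genome))
  stopifnot(length(g) == 1L)
  if (is.character(intervals)) intervals <- .parse_spans(intervals)
  if (is.character(exclusions)) exclusions <- .parse_spans(exclusions)
  if (is.null(exclusions)) exclusions <- .parse_spans("")
  .validate_entry(intervals, genes, if (is.null(id)) "<genome>" else id)
  len <- nchar(g)
  if (any(intervals[, 2L] > len) ||
      (nrow(exclusions) && any(exclusions[, 2L] > len))) {
    stop("coordinate out of range (genome length ", len, ")", call. = FALSE)
  }
  o <- order(intervals[, 1L])
  intervals <- intervals[o, , drop = FALSE]
  if (!is.null(genes)) genes <- genes[o]
  pieces <- character(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    s <- intervals[i, 1L]; e <- intervals[i, 2L]
    keep <- rep(TRUE, e - s + 1L)
    if (nrow(exclusions)) {
      for (j in seq_len(nrow(exclusions))) {
        xs <- max(exclusions[j, 1L], s); xe <- min(exclusions[j, 2L], e)
        if (xs <= xe) keep[(xs - s + 1L):(xe - s + 1L)] <- FALSE
      }
    }
    piece <- paste(strsplit(substr(g, s, e), "")[[1L]][keep], collapse = "")
    if (nchar(piece) %% 3L != 0L) {
      stop("entry '", if (is.null(id)) "<genome>" else id, "', interval ",
           s, "-", e, ": length ", nchar(piece),
           " after exclusion subtraction is not divisible by 3",
           call. = FALSE)
    }
    pieces[i] <- piece
  }
  names(pieces) <- if (!is.null(genes)) genes else paste0("piece", seq_along(pieces))
  piece_counts <- lapply(seq_along(pieces), function(i) {
    count_codons(pieces[i], policy = "strict",
                 id = paste0(if (is.null(id)) "" else paste0(id, ":"),
                             names(pieces)[i]))
  })
  names(piece_counts) <- names(pieces)
  counts <- pool_counts(piece_counts, id = id)
  structure(
    list(pieces = pieces, sequence = paste(pieces, collapse = ""),
         counts = counts, piece_counts = piece_counts,
         record_id = if (is.null(id)) NA_character_ else id),
    class = "coding_region"
  )
}

#' @export
print.coding_region <- function(x, ...) {
  cat("Coding region",
      if (!is.na(x$record_id)) paste0("[", x$record_id, "]"),
      "-", length(x$pieces), "piece(s),", nchar(x$sequence), "nt\n")
  invisible(x)
}

#' Load a host codon-usage table
#'
#' Reads a per-cell-type usage table: a CSV/TSV whose first column
#' (\code{codon}) holds uppercase DNA codons and whose second column holds
#' either raw codon counts or RSCU values. ATG, TGG and stop codons, if
#' present, are dropped with a message (usage statistics are defined over the
#' 59 synonymous codons); after that all 59 codons must be present exactly
#' once with non-negative values. Counts are converted to RSCU internally via
#' \code{\link{rscu}}.
#'
#' @param path Path to the table (separator sniffed: tab if the header
#'   contains one, comma otherwise).
#' @param format \code{"rscu"} or \code{"counts"}.
#' @param cell_type Label; defaults to the value column's name.
#' @return An object of class \code{"host_usage"}: list with
#'   \code{cell_type}, \code{rscu} (named over the 59 codons),
#'   \code{counts} (named, or \code{NULL} when the file held RSCU),
#'   \code{n_genes} (NA unless recorded elsewhere), \code{source}.
#' @export
load_host_table <- function(path, format = c("rscu", "counts"),
                            cell_type = NULL) {
  format <- match.arg(format)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L || tolower(names(df)[1L]) != "codon") {
    stop("expected a header 'codon' plus one value column", call. = FALSE)
  }
  if (is.null(cell_type)) cell_type <- names(df)[2L]
  codons <- chartr("U", "T", toupper(df[[1L]]))
  values <- df[[2L]]
  code <- genetic_code()
  drop <- codons %in% c("ATG", "TGG", code$stop_codons)
  if (any(drop)) {
    message("dropping non-synonymous/stop codon(s) from host table: ",
            paste(codons[drop], collapse = ", "))
    codons <- codons[!drop]; values <- values[!drop]
  }
  if (anyDuplicated(codons)) {
    stop("duplicated codon(s): ",
         paste(unique(codons[duplicated(codons)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(code$synonymous_codons, codons)
  if (length(missing)) {
    stop("host table lacks codon(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(codons, code$synonymous_codons)
  if (length(extra)) {
    stop("not synonymous codons: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (any(values < 0) || anyNA(values)) {
    stop("host table values must be non-negative and complete", call. = FALSE)
  }
  values <- stats::setNames(values, codons)[code$synonymous_codons]
  if (format == "counts") {
    cnt <- codon_counts(round(values), id = cell_type)
    new_host_usage(cell_type, rscu(cnt)$values, counts = values,
                   source = path)
  } else {
    new_host_usage(cell_type, values, counts = NULL, source = path)
  }
}

new_host_usage <- function(cell_type, rscu_values, counts = NULL,
                           source = NA_character_, n_genes = NA_integer_) {
  structure(
    list(cell_type = cell_type, rscu = rscu_values, counts = counts,
         n_genes = n_genes, source = source),
    class = "host_usage"
  )
}

#' @export
print.host_usage <- function(x, ...) {
  cat("Host codon-usage table [", x$cell_type, "] - 59 synonymous codons",
      if (!is.null(x$counts)) paste0("(", format(sum(x$counts), big.mark = ","),
                                     " codon occurrences)"), "\n")
  cat("  A/T-ending share:", round(at_ending_fraction(x), 1), "%\n")
  invisible(x)
}

#' Write a host usage table (RSCU form)
#'
#' Full-precision writer so that a written table re-loads value-identical.
#'
#' @param x A \code{"host_usage"} object.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_host_table <- function(x, path) {
  stopifnot(inherits(x, "host_usage"))
  lines <- c(paste0("codon,", x$cell_type),
             paste0(names(x$rscu), ",", sprintf("%.17g", x$rscu)))
  writeLines(lines, path)
  invisible(path)
}

#' Fraction of A/T-ending synonymous codon occurrences
#'
#' The percentage of synonymous-codon occurrences whose third base is A or T.
#' For objects carrying counts the share is occurrence-weighted directly. For
#' RSCU-only inputs (host tables without counts, RSCU profiles) the amino
#' acid frequencies are unknown, so the share is the RSCU-weighted value
#' under equal family occupancy: the mean over families of
#' (sum of RSCU over A/T-ending synonyms)/D, times 100.
#'
#' @param x A \code{"codon_counts"}, \code{"host_usage"} or
#'   \code{"rscu_profile"} object.
#' @return A percentage in [0, 100].
#' @examples
#' at_ending_fraction(codon_counts(c(GCA = 1, GCG = 1)))  # 50
#' @export
at_ending_fraction <- function(x) UseMethod("at_ending_fraction")

.at_ending_codons <- function() {
  code <- genetic_code()
  syn <- code$synonymous_codons
  syn[substr(syn, 3L, 3L) %in% c("A", "T")]
}

#' @export
at_ending_fraction.codon_counts <- function(x) {
  code <- genetic_code()
  total <- sum(x$counts[code$synonymous_codons])
  if (total == 0) stop("no synonymous codons observed", call. = FALSE)
  100 * sum(x$counts[.at_ending_codons()]) / total
}

#' @export
at_ending_fraction.host_usage <- function(x) {
  if (!is.null(x$counts)) {
    total <- sum(x$counts)
    if (total == 0) stop("zero total count", call. = FALSE)
    return(100 * sum(x$counts[.at_ending_codons()]) / total)
  }
  .at_share_from_rscu(x$rscu)
}

#' @export
at_ending_fraction.rscu_profile <- function(x) {
  code <- genetic_code()
  keep <- setdiff(code$degenerate_aa, x$undefined_families)
  if (!length(keep)) stop("all families undefined", call. = FALSE)
  .at_share_from_rscu(x$values, families = keep)
}

.at_share_from_rscu <- function(values, families = NULL) {
  code <- genetic_code()
  if (is.null(families)) families <- code$degenerate_aa
  at <- .at_ending_codons()
  shares <- vapply(families, function(a) {
    syn <- code$synonym_families[[a]]
    sum(values[intersect(syn, at)]) / length(syn)
  }, numeric(1))
  100 * mean(shares)
}
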