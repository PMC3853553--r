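# File formats: FASTA/FASTQ via Biostrings, tab-separated tables with headers.
# All readers return tibbles; all sequences are uppercased on input.

#' Read a FASTA file into a tibble
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return tibble with columns `id` (first whitespace-delimited token of the
#'   header), `desc` (full header) and `seq` (uppercase DNA).
#' @export
read_fasta <- function(path) {
  check_fasta_headers(path)
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  headers <- names(x)
  tibble(
    id = sub("\\s.*$", "", headers),
    desc = headers,
    seq = toupper(as.character(x, use.names = FALSE))
  )
}

#' Read a FASTQ file into a tibble
#'
#' Qualities are carried along but ignored by every downstream step: the
#' pipeline does no quality filtering.
#'
#' @param path path to a FASTQ file.
#' @return tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = sub("\\s.*$", "", names(x)),
    seq = toupper(as.character(x, use.names = FALSE)),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Write sequences to FASTA
#'
#' @param x tibble with columns `id` and `seq`; any further columns are
#'   appended to the header as `key=value` pairs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  extra <- setdiff(names(x), c("id", "seq", "desc", "qual"))
  headers <- x$id
  if (length(extra)) {
    kv <- purrr::map_chr(seq_len(nrow(x)), function(i) {
      paste(sprintf("%s=%s", extra, purrr::map_chr(extra, ~ as.character(x[[.x]][i]))),
            collapse = " ")
    })
    headers <- paste(headers, kv)
  }
  set <- Biostrings::DNAStringSet(x$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Write a FASTQ file
#'
#' @param x tibble with columns `id`, `seq` and optionally `qual` (defaults
#'   to maximal Phred 'I' if absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  qual <- x$qual %||% strrep("I", nchar(x$seq))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", x$id, "\n", x$seq, "\n+\n", qual), con)
  invisible(path)
}

# FASTA sanity check with a line-numbered error for a malformed header.
check_fasta_headers <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonempty <- which(nzchar(lines))
  if (!length(nonempty)) return(invisible(TRUE))
  first <- nonempty[1]
  if (!startsWith(lines[first], ">")) {
    abort(sprintf("malformed FASTA: line %d does not start with '>'", first))
  }
  invisible(TRUE)
}

#' Read a taxonomy table
#'
#' Expects a TSV with header `species_id  genus  family  origin`; `origin` is
#' one of `native`, `introduced`, `both`.
#'
#' @param path path to the TSV file.
#' @return taxonomy tibble (validated, see [validate_taxonomy()]).
#' @export
read_taxonomy <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_taxonomy(as_tibble(x))
}

#' Validate a taxonomy tibble
#'
#' Checks the rank tree: every species has exactly one genus and one family,
#' genus names nest uniquely within families, and species ids are unique
#' (duplicates are a hard error, never silently dropped).
#'
#' @param tax tibble with columns `species_id`, `genus`, `family`, `origin`.
#' @return the validated tibble.
#' @export
validate_taxonomy <- function(tax) {
  need <- c("species_id", "genus", "family", "origin")
  missing <- setdiff(need, names(tax))
  if (length(missing)) {
    abort(paste("taxonomy is missing columns:", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tax$species_id)) {
    dup <- unique(tax$species_id[duplicated(tax$species_id)])
    abort(paste("duplicate species_id in taxonomy:", paste(dup, collapse = ", ")))
  }
  bad_origin <- setdiff(unique(tax$origin), c("native", "introduced", "both"))
  if (length(bad_origin)) {
    abort(paste("unknown origin values:", paste(bad_origin, collapse = ", ")))
  }
  fam_per_genus <- tax |> distinct(.data$genus, .data$family) |> count(.data$genus)
  if (any(fam_per_genus$n > 1)) {
    abort(paste(
      "genus assigned to more than one family:",
      paste(fam_per_genus$genus[fam_per_genus$n > 1], collapse = ", ")
    ))
  }
  as_tibble(tax)
}

#' Read a MID tag map
#'
#' TSV with header `mid_tag  sample_id`. Tags must be prefix-unique (no tag a
#' prefix of another); violations are a configuration error at load time.
#'
#' @param path path to the TSV file.
#' @return tibble with columns `mid_tag`, `sample_id`.
#' @export
read_mid_map <- function(path) {
  x <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  validate_mid_map(x)
}

#' Validate a MID map tibble
#' @param mids tibble with columns `mid_tag`, `sample_id`.
#' @return the validated tibble with uppercased tags.
#' @export
validate_mid_map <- function(mids) {
  stopifnot(all(c("mid_tag", "sample_id") %in% names(mids)))
  mids$mid_tag <- check_dna(mids$mid_tag, "MID tag")
  if (anyDuplicated(mids$sample_id)) abort("duplicate sample_id in MID map")
  tags <- mids$mid_tag
  for (i in seq_along(tags)) {
    pref <- startsWith(tags, tags[i])
    pref[i] <- FALSE
    if (any(pref)) {
      abort(sprintf(
        "MID map is not prefix-unique: '%s' is a prefix of '%s'",
        tags[i], tags[which(pref)[1]]
      ))
    }
  }
  mids
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `island`, `collection_date` (ISO-8601),
#' `collection_mode`, and optionally `host_confirmed`. A `month` column
#' (integer 1-12) is derived from the date, locale-independently.
#'
#' @param path path to the TSV file.
#' @return metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  x <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("sample_id", "island", "collection_date") %in% names(x)))
  x$collection_date <- as.Date(x$collection_date)
  x$month <- as.integer(format(x$collection_date, "%m"))
  x
}

#' Write a tibble as TSV
#'
#' Tab-separated, header row, no quoting or row names; the plain-text
#' interchange format used by every stage of the pipeline.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
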