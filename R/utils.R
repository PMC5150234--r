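#' Read a FASTA file into a sequence record table
#'
#' Headers of the form `sample|cluster|index` (the convention used by
#' [generate_sequences()]) are split into `sample` and `cluster` columns;
#' any other header is kept verbatim as the id with `sample = NA`.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A data.frame with columns `id`, `sample`, `cluster`, `bases`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  parts <- strsplit(ids, "|", fixed = TRUE)
  has3 <- vapply(parts, length, integer(1)) == 3L
  data.frame(
    id = ids,
    sample = ifelse(has3, vapply(parts, `[`, "", 1L), NA_character_),
    cluster = ifelse(has3, vapply(parts, `[`, "", 2L), NA_character_),
    bases = toupper(as.character(ss)),
    stringsAsFactors = FALSE
  )
}

#' Write sequence records to FASTA
#'
#' @param records Data.frame with columns `id` and `bases`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "bases") %in% names(records)))
  ss <- Biostrings::DNAStringSet(records$bases)
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# Validate a sequence record data.frame (id/sample/bases columns).
check_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("id", "sample", "bases")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(records$id)) stop("sequence ids must be unique")
  if (any(!nzchar(records$bases))) stop("empty sequence in records")
  bad <- grepl("[^ACGTN-]", records$bases)
  if (any(bad)) {
    stop("sequence alphabet must be ACGTN-: offending id ",
         records$id[which(bad)[1]])
  }
  invisible(records)
}

# Scalar checks used by the spec constructors.
check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be a single number")
  }
  if (strict_min && x <= min) stop(name, " must be > ", min)
  if (!strict_min && x < min) stop(name, " must be >= ", min)
  invisible(x)
}
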