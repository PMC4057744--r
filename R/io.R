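# Readers/writers and coordinate mapping.
#
# Alignments are aligned protein FASTA (gaps "-", "." normalised to "-");
# the first record is the reference (human) protein unless another id is
# named. Variant tables are delimited text with columns gene, position
# (1-based in the ungapped reference), wild-type, variant, label. Alignment
# columns are 0-based internally and never exposed raw.

#' Construct an alignment object
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (upper case, gaps as `-`).
#' @param reference Index of the reference record (default 1).
#' @return An object of class `gm_alignment`: list with `ids`, `seqs`,
#'   `depth`, `length` (columns), `reference`.
#' @export
gm_alignment <- function(seqs, reference = 1L) {
  if (length(seqs) < 1L) stop("alignment must contain at least one record",
                              call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  seqs <- toupper(unname(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    off <- ids[widths != widths[1L]][1L]
    stop("ragged alignment: record '", off, "' has a different length",
         call. = FALSE)
  }
  ref <- seqs[reference]
  if (!grepl("[^-]", ref))
    stop("reference record contains no residues", call. = FALSE)
  structure(
    list(ids = ids, seqs = seqs, depth = length(seqs),
         length = widths[1L], reference = as.integer(reference)),
    class = "gm_alignment"
  )
}

#' @export
print.gm_alignment <- function(x, ...) {
  cat("Protein alignment:", x$depth, "sequences x", x$length, "columns;",
      "reference:", x$ids[x$reference], "\n")
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' Mixed-case input is upper-cased and `.` gaps are normalised to `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @param reference_id Optional record id to use as the reference protein;
#'   defaults to the first record.
#' @return A [gm_alignment()] object.
#' @export
read_alignment <- function(path, reference_id = NULL) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot read FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  ref <- 1L
  if (!is.null(reference_id)) {
    ref <- match(reference_id, names(seqs))
    if (is.na(ref)) stop("reference id '", reference_id, "' not in alignment",
                         call. = FALSE)
  }
  gm_alignment(seqs, reference = ref)
}

#' Write an alignment to FASTA
#'
#' @param aln A [gm_alignment()] object.
#' @param path Output file.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::AAStringSet(stats::setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Map a reference protein position to an alignment column
#'
#' Returns the 0-based alignment column holding the `position`-th non-gap
#' residue of the reference sequence. Strictly increasing in `position`.
#'
#' @param aln A [gm_alignment()] object.
#' @param position 1-based position in the ungapped reference protein.
#' @return 0-based column index (integer).
#' @export
map_position <- function(aln, position) {
  ref <- strsplit(aln$seqs[aln$reference], "")[[1L]]
  nongap <- which(ref != "-")
  if (!is.numeric(position) || length(position) != 1L || is.na(position) ||
      position < 1 || position != round(position))
    stop("`position` must be a positive integer", call. = FALSE)
  if (position > length(nongap))
    stop("position ", position, " is beyond the ungapped reference length (",
         length(nongap), ")", call. = FALSE)
  nongap[position] - 1L
}

# residues of one alignment column (0-based index), gaps retained
column_residues <- function(aln, column) {
  substring(aln$seqs, column + 1L, column + 1L)
}

LABEL_TOKENS <- list(
  D = c("d", "deleterious", "1"),
  N = c("n", "neutral", "0"),
  unknown = c("unknown", "u", "?", "na", "")
)

normalise_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  for (lab in names(LABEL_TOKENS)) out[x %in% LABEL_TOKENS[[lab]]] <- lab
  if (anyNA(out))
    stop("unknown variant label token(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Read a variant table
#'
#' Tab- or comma-delimited text with header columns `gene`, `position`,
#' `wt`, `variant`, `label`. Labels accept `D`/`deleterious`/`1`,
#' `N`/`neutral`/`0` and `unknown` (case-insensitive). Synonymous rows
#' (`wt == variant`) are rejected. When an alignment is supplied, each
#' stated wild-type is cross-checked against the mapped reference residue;
#' mismatches warn (and keep the stated wild-type) or error under
#' `strict = TRUE`.
#'
#' @param path Path to the variant table.
#' @param alignment Optional [gm_alignment()] for wild-type validation.
#' @param strict Escalate wild-type/reference mismatches to errors.
#' @return A data frame with columns `gene`, `position`, `wt`, `variant`,
#'   `label`.
#' @export
read_variants <- function(path, alignment = NULL, strict = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  names(tab) <- tolower(names(tab))
  need <- c("gene", "position", "wt", "variant", "label")
  if (!all(need %in% names(tab)))
    stop("variant table must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  out <- data.frame(
    gene = as.character(tab$gene),
    position = as.integer(tab$position),
    wt = check_residues(tab$wt, "wild-type"),
    variant = check_residues(tab$variant, "variant"),
    label = normalise_label(tab$label),
    stringsAsFactors = FALSE
  )
  if (any(out$wt == out$variant)) {
    i <- which(out$wt == out$variant)[1L]
    stop("synonymous variant at row ", i, " (", out$gene[i], " p.",
         out$wt[i], out$position[i], out$variant[i],
         "): wild-type and variant are identical", call. = FALSE)
  }
  if (!is.null(alignment)) validate_wildtypes(out, alignment, strict = strict)
  out
}

validate_wildtypes <- function(variants, alignment, strict = FALSE) {
  for (i in seq_len(nrow(variants))) {
    col <- map_position(alignment, variants$position[i])
    ref_res <- column_residues(alignment, col)[alignment$reference]
    if (ref_res != variants$wt[i]) {
      msg <- paste0("variant ", variants$gene[i], " p.", variants$wt[i],
                    variants$position[i], variants$variant[i],
                    ": stated wild-type ", variants$wt[i],
                    " differs from reference residue ", ref_res)
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  invisible(variants)
}

#' Write a variant (or scored-variant) table
#'
#' @param variants Data frame as returned by [read_variants()] or
#'   [predict.gm_model()].
#' @param path Output file (tab-delimited).
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Save a trained gene model
#'
#' Serialises a [gm_model] to a flat YAML document (parameters, class
#' means/SDs, cluster index, cut-off, calibration provenance).
#'
#' @param model A `gm_model` object.
#' @param path Output file.
#' @export
write_gm_model <- function(model, path) {
  stopifnot(inherits(model, "gm_model"))
  doc <- list(
    format = "gmetric-gene-model",
    version = 1L,
    gene = model$gene,
    params = as.list(model$params),
    mean_d = model$mean_d, mean_n = model$mean_n,
    sd_d = model$sd_d, sd_n = model$sd_n,
    r_index = model$r_index, cutoff = model$cutoff,
    valid_orientation = model$valid_orientation,
    n_deleterious = model$n_deleterious, n_neutral = model$n_neutral,
    deflate_convention = paste0("zlib-minus-", DEFLATE_OVERHEAD)
  )
  writeLines(yaml::as.yaml(doc, precision = 15L), path)
  invisible(path)
}

#' Load a trained gene model
#'
#' @param path Path to a YAML document written by [write_gm_model()].
#' @return A `gm_model` object.
#' @export
read_gm_model <- function(path) {
  if (!file.exists(path))
    stop("cannot read model file '", path, "': no such file", call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "gmetric-gene-model"))
    stop("'", path, "' is not a gmetric gene-model document", call. = FALSE)
  new_gm_model(
    params = doc$params,
    mean_d = doc$mean_d, mean_n = doc$mean_n,
    sd_d = doc$sd_d, sd_n = doc$sd_n,
    gene = doc$gene,
    n_deleterious = doc$n_deleterious, n_neutral = doc$n_neutral
  )
}
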