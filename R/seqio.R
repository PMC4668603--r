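## Sequence and label input/output.  All encoders assume sequences that
## passed validateProteins(), i.e. uppercase strings over the 20 standard
## residues.

#' Validate protein sequences against the 20-letter alphabet
#'
#' Residues are uppercased, then non-standard letters (B, J, O, U, X, Z,
#' `*`, gaps, ...) are handled according to `policy`:
#' \describe{
#'   \item{`"strip-residue"`}{(default) offending letters are removed and
#'     a warning names the affected records; records left empty are
#'     dropped with a warning.}
#'   \item{`"skip-record"`}{any record containing a non-standard letter
#'     is dropped with a warning.}
#'   \item{`"strict"`}{the first offending record raises an error.}
#' }
#' Validation is idempotent: applying a policy to an already valid set is
#' the identity.
#'
#' @param x An [Biostrings::AAStringSet] or named character vector.
#' @param policy One of `"strip-residue"`, `"skip-record"`, `"strict"`.
#' @return A validated `AAStringSet`.
#' @export
validateProteins <- function(x,
    policy = c("strip-residue", "skip-record", "strict")) {
  policy <- match.arg(policy)
  seqs <- toupper(as.character(x))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("sequences must carry non-empty ids")
  pattern <- sprintf("[^%s]", paste(AA20, collapse = ""))
  bad <- grepl(pattern, seqs)
  if (any(bad)) {
    offenders <- ids[bad]
    if (policy == "strict") {
      stop("non-standard residues in record(s): ",
           paste(offenders, collapse = ", "))
    } else if (policy == "skip-record") {
      warning("dropped ", sum(bad), " record(s) with non-standard residues: ",
              paste(offenders, collapse = ", "))
      seqs <- seqs[!bad]
      ids <- ids[!bad]
    } else {
      warning("stripped non-standard residues from ", sum(bad),
              " record(s): ", paste(offenders, collapse = ", "))
      seqs[bad] <- gsub(pattern, "", seqs[bad])
      empty <- !nzchar(seqs)
      if (any(empty)) {
        warning("dropped ", sum(empty),
                " record(s) left empty after stripping: ",
                paste(ids[empty], collapse = ", "))
        seqs <- seqs[!empty]
        ids <- ids[!empty]
      }
    }
  }
  Biostrings::AAStringSet(stats::setNames(seqs, ids))
}

#' Read and validate a protein FASTA file
#'
#' Sequence ids are the first whitespace-delimited token of each header.
#' Lowercase residues are uppercased; non-standard residues are handled
#' per `policy` (see [validateProteins()]).
#'
#' @param path Path to a FASTA file.
#' @param policy Residue policy passed to [validateProteins()].
#' @return An [Biostrings::AAStringSet] of validated records in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 some description", "MKV"), fa)
#' readProteinFasta(fa)
#' @export
readProteinFasta <- function(path,
    policy = c("strip-residue", "skip-record", "strict")) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (!length(first)) stop("empty FASTA file: ", path)
  if (!startsWith(first[1L], ">"))
    stop("malformed FASTA (no '>' header before sequence): ", path)
  x <- Biostrings::readAAStringSet(path)
  if (!length(x)) stop("empty FASTA file: ", path)
  ids <- sub("[ \t].*$", "", names(x))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  names(x) <- ids
  validateProteins(x, policy)
}

#' Write protein sequences to FASTA
#'
#' @param x An `AAStringSet` or named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProteinFasta <- function(x, path) {
  if (!is(x, "AAStringSet")) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a tab-delimited label file
#'
#' Two columns, no header: sequence id and class label.
#'
#' @param path Path to the label file.
#' @param labelSet Character vector of admissible labels (e.g.
#'   `c("0", "1")` or `c("NR1", ..., "NR8")`); `NULL` accepts any label.
#' @return Named character vector mapping id to label.
#' @examples
#' f <- tempfile()
#' writeLines(c("s1\t1", "s2\t0"), f)
#' readLabels(f, labelSet = c("0", "1"))
#' @export
readLabels <- function(path, labelSet = NULL) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("id", "label"))
  if (!nrow(tab)) stop("empty label file: ", path)
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup))
    stop("repeated id(s) in label file: ", paste(dup, collapse = ", "))
  if (!is.null(labelSet)) {
    bad <- which(!tab$label %in% labelSet)
    if (length(bad))
      stop("label outside declared set on line ", bad[1L], ": '",
           tab$label[bad[1L]], "' (id ", tab$id[bad[1L]], ")")
  }
  stats::setNames(tab$label, tab$id)
}

#' Parse class labels from FASTA headers
#'
#' Alternative to a separate label file: headers of the form
#' `>id<delim>label` yield the label as the field after the first
#' delimiter.
#'
#' @param headers Character vector of full FASTA headers (without `>`).
#' @param delim Single-character field delimiter (default `"|"`).
#' @param labelSet Optional admissible labels, as in [readLabels()].
#' @return Named character vector mapping id to label.
#' @export
parseHeaderLabels <- function(headers, delim = "|", labelSet = NULL) {
  parts <- strsplit(headers, delim, fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("header(s) without a '", delim, "'-delimited label field")
  ids <- sub("[ \t].*$", "", vapply(parts, `[`, "", 1L))
  labels <- sub("[ \t].*$", "", trimws(vapply(parts, `[`, "", 2L)))
  if (!is.null(labelSet)) {
    bad <- which(!labels %in% labelSet)
    if (length(bad))
      stop("label outside declared set: '", labels[bad[1L]], "' (id ",
           ids[bad[1L]], ")")
  }
  stats::setNames(labels, ids)
}

#' Write a feature matrix to a tab-delimited file
#'
#' First column `id`, then one column per feature named by its stable
#' feature label (for CTF, triad strings such as `"C-RK-AGV"`).  A
#' comment line records the feature-set identity so the file round-trips
#' through [readFeatureMatrix()].
#'
#' @param features A [ProteinFeatures-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFeatureMatrix <- function(features, path) {
  stopifnot(is(features, "ProteinFeatures"))
  v <- featureValues(features)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#feature_set=%s", featureSet(features)), con)
  writeLines(paste(c("id", colnames(v)), collapse = "\t"), con)
  utils::write.table(
    data.frame(id = rownames(v), v, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureMatrix()]
#'
#' @param path Path to the tab-delimited matrix.
#' @return A [ProteinFeatures-class].
#' @export
readFeatureMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  fs <- if (startsWith(first, "#feature_set="))
    sub("^#feature_set=", "", first) else "custom"
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  new("ProteinFeatures", values = m, featureSet = fs)
}
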