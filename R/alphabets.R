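#' Construct an amino-acid alphabet partition
#'
#' @param name Identifier for the partition.
#' @param groups Named list of character vectors of single-letter residue
#'   codes; groups must be disjoint and cover all 20 standard residues.
#' @return An [AminoAlphabet-class].
#' @examples
#' twoClass <- AminoAlphabet("hydrophobic-split", list(
#'   HP = c("A","C","F","G","I","L","M","P","V","W"),
#'   PO = c("D","E","H","K","N","Q","R","S","T","Y")))
#' nGroups(twoClass)
#' @export
AminoAlphabet <- function(name, groups) {
  groups <- lapply(groups, function(g) toupper(as.character(g)))
  new("AminoAlphabet", name = name, groups = groups)
}

#' The seven-class conjoint-triad alphabet
#'
#' The 20 amino acids grouped into seven classes by the dipole and volume
#' of their side chains: \{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\},
#' \{H,N,Q,W\}, \{R,K\}, \{D,E\}, \{C\}.  Residues within a class are
#' treated as identical when counting triads.
#'
#' @return An [AminoAlphabet-class] with 7 groups.
#' @examples
#' classOf(ctfAlphabet())[c("A", "C", "R")]
#' @export
ctfAlphabet <- function() {
  AminoAlphabet("ctf7", list(
    AGV  = c("A", "G", "V"),
    ILFP = c("I", "L", "F", "P"),
    YMTS = c("Y", "M", "T", "S"),
    HNQW = c("H", "N", "Q", "W"),
    RK   = c("R", "K"),
    DE   = c("D", "E"),
    C    = "C"))
}

#' The default 12-group chaos-game vertex alphabet
#'
#' Assigns the 20 residues to the 12 vertices of the chaos-game polygon.
#' The grouping follows conservative-substitution classes (small/special
#' residues alone; chemically similar residues pooled) and is an
#' approximation of the historical 12-vertex scheme, which was never
#' published in full; any 12-group [AminoAlphabet-class] can be
#' substituted via the `alphabet` arguments of the CGR functions.
#'
#' @return An [AminoAlphabet-class] with 12 groups (vertex k = group k).
#' @export
cgrAlphabet <- function() {
  AminoAlphabet("cgr12", list(
    A   = "A",
    G   = "G",
    P   = "P",
    C   = "C",
    ST  = c("S", "T"),
    DE  = c("D", "E"),
    NQ  = c("N", "Q"),
    H   = "H",
    KR  = c("K", "R"),
    M   = "M",
    ILV = c("I", "L", "V"),
    FYW = c("F", "Y", "W")))
}

#' Read an alphabet partition from a text file
#'
#' One group per line: the group label, whitespace or tab, then the
#' residues as a comma-separated list (or a bare string of letters).
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the config file.
#' @param name Alphabet name; defaults to the file name.
#' @return An [AminoAlphabet-class].
#' @export
readAlphabet <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("alphabet file '", path, "' defines no groups")
  groups <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) < 2L)
      stop("malformed alphabet line: '", ln, "'")
    res <- unlist(strsplit(parts[-1L], ","))
    res <- unlist(strsplit(res, ""))  # allow "AGV" as well as "A,G,V"
    groups[[parts[1L]]] <- res
  }
  AminoAlphabet(name, groups)
}

#' Write an alphabet partition to a text file
#'
#' Inverse of [readAlphabet()].
#'
#' @param alphabet An [AminoAlphabet-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeAlphabet <- function(alphabet, path) {
  stopifnot(is(alphabet, "AminoAlphabet"))
  lines <- sprintf("%s\t%s", names(alphabet@groups),
                   vapply(alphabet@groups, paste, "", collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
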