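#' Local/parent position conversion for a filter window
#'
#' The seven filter residues use local numbering 1-7; `localPosition` maps a
#' parent-sequence index into that window and `parentPosition` is its
#' inverse. Positions outside the window are an error.
#'
#' @param filter a [FilterSequence-class].
#' @param parentPos parent-sequence index.
#' @param localPos local index in 1-7.
#' @return integer position.
#' @examples
#' cavmr <- filterSequence("TLEGWVD", 183, "CavMr")
#' localPosition(cavmr, 183)  # 1 (Thr1)
#' localPosition(cavmr, 189)  # 7 (Asp7)
#' parentPosition(cavmr, 4)   # 186
#' @export
localPosition <- function(filter, parentPos) {
  p <- parentPos - filter@parentOffset + 1L
  if (any(p < 1L | p > 7L))
    stop("localPosition: parent position ", parentPos,
         " is outside the filter window ", filter@parentOffset, "-",
         filter@parentOffset + 6L)
  as.integer(p)
}

#' @rdname localPosition
#' @export
parentPosition <- function(filter, localPos) {
  if (any(localPos < 1L | localPos > 7L))
    stop("parentPosition: local position must be in 1-7")
  as.integer(filter@parentOffset + localPos - 1L)
}

#' Apply point mutations to a filter sequence
#'
#' Mutation codes use the standard <ref><pos><alt> form (e.g. "G4D",
#' "T6S"). Positions are local (1-7) by default; full-protein numbering
#' (e.g. "G240A") is accepted with `numbering = "parent"`, in which case the
#' position is translated through the window's parent offset. Multiple codes
#' (vector, or one string separated by "/", "+", "," or spaces) are applied
#' left to right. The reference residue must match the current sequence at
#' the stated position, otherwise a mismatch error quoting both residues is
#' raised.
#'
#' @param filter a [FilterSequence-class].
#' @param mutation mutation code(s).
#' @param numbering "local" (1-7) or "parent".
#' @return the mutated [FilterSequence-class]; the label gains a "-<code>"
#'   suffix.
#' @examples
#' navpp <- filterSequence("TLEDWTD", label = "NavPp")
#' filterResidues(applyMutation(navpp, "T6S"))  # "TLEDWSD"
#' @export
applyMutation <- function(filter, mutation, numbering = c("local", "parent")) {
  numbering <- match.arg(numbering)
  codes <- unlist(strsplit(mutation, "[/+, ]+"))
  res <- strsplit(filter@residues, "")[[1]]
  for (code in codes) {
    m <- regmatches(code, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", code))[[1]]
    if (length(m) != 4L)
      stop("applyMutation: malformed mutation code '", code, "'")
    ref <- toupper(m[2]); pos <- as.integer(m[3]); alt <- toupper(m[4])
    if (numbering == "parent") pos <- localPosition(filter, pos)
    if (pos < 1L || pos > 7L)
      stop("applyMutation: position ", pos, " outside the 7-residue window")
    if (res[pos] != ref)
      stop("applyMutation: reference mismatch for '", code, "': filter has '",
           res[pos], "' at position ", pos, ", code expects '", ref, "'")
    res[pos] <- alt
  }
  filterSequence(paste(res, collapse = ""), filter@parentOffset,
                 label = if (nzchar(filter@label))
                   paste0(filter@label, "-", paste(codes, collapse = "/"))
                 else paste(codes, collapse = "/"))
}

#' Acidic-residue charge accounting for a filter assembly
#'
#' Counts aspartates (D) and total acidic residues (D + E, the net negative
#' charge; no positively charged residues occur in these filters) per
#' subunit, and multiplies by the number of subunits of the homotetramer.
#' For heteromeric assemblies, pass a list of four filters: per-subunit
#' counts are summed with one subunit each.
#'
#' @param filter a [FilterSequence-class], a 7-residue string, or a list of
#'   them (heteromer).
#' @param nSubunits subunits per assembly (4 for homotetramers; forced to 1
#'   per element when a list is given).
#' @return named list: `acidicPerSubunit`, `aspartatesPerAssembly`,
#'   `netNegativePerAssembly`.
#' @examples
#' chargeCount("TLEGWVD")  # CavMr: 4 aspartates, net negative 8
#' chargeCount("TLDDWSD")  # CavAb-type: net negative 12
#' @export
chargeCount <- function(filter, nSubunits = 4) {
  asString <- function(f) if (is(f, "FilterSequence")) f@residues
  else filterSequence(f)@residues  # validates
  if (is.list(filter)) {
    parts <- lapply(filter, chargeCount, nSubunits = 1)
    return(list(
      acidicPerSubunit = vapply(parts, `[[`, numeric(1), "acidicPerSubunit"),
      aspartatesPerAssembly =
        sum(vapply(parts, `[[`, numeric(1), "aspartatesPerAssembly")),
      netNegativePerAssembly =
        sum(vapply(parts, `[[`, numeric(1), "netNegativePerAssembly"))))
  }
  aa <- strsplit(asString(filter), "")[[1]]
  nD <- sum(aa == "D")
  nAcidic <- sum(aa %in% c("D", "E"))
  list(acidicPerSubunit = nAcidic,
       aspartatesPerAssembly = nD * nSubunits,
       netNegativePerAssembly = nAcidic * nSubunits)
}

#' Per-position amino-acid frequency matrix
#'
#' Relative frequency of each amino acid at each of the 7 filter positions
#' across a set of filter sequences; every column sums to 1.
#'
#' @param filters list of [FilterSequence-class] (or 7-residue strings).
#' @return 20 x 7 matrix (rows = amino acids in [Biostrings::AA_STANDARD]
#'   order, columns pos1-pos7) with attribute `n_sequences`.
#' @examples
#' fm <- frequencyMatrix(list("TLEGWVD", "TLEDWTD"))
#' fm["G", 4]; fm["D", 4]  # 0.5 each
#' @export
frequencyMatrix <- function(filters) {
  if (length(filters) == 0L) stop("frequencyMatrix: empty input")
  if (!is.list(filters)) filters <- as.list(filters)
  seqs <- vapply(filters, function(f)
    if (is(f, "FilterSequence")) f@residues else filterSequence(f)@residues,
    character(1))
  aa <- Biostrings::AA_STANDARD
  m <- matrix(0, nrow = length(aa), ncol = 7,
              dimnames = list(aa, paste0("pos", 1:7)))
  for (s in seqs) {
    r <- strsplit(s, "")[[1]]
    for (p in 1:7) m[r[p], p] <- m[r[p], p] + 1
  }
  m <- m / length(seqs)
  attr(m, "n_sequences") <- length(seqs)
  m
}

#' Built-in selectivity-filter sequences
#'
#' The filter strings of the channels discussed in this package's analyses:
#' the AnclNav-family CavMr (183-TLEGWVD-189) and NavPp (TLEDWTD) and their
#' mutants, the engineered calcium-selective BacNav filters (TLDDWSD,
#' TLDDWAD), the Bacillus-type sodium filter (TLESWAS) and its NsvBa variant
#' (TLDSWGS), and the CatSper 3/4 filters (TVDGWTD, TQDGWVD). Parent offsets
#' are recorded where published (CavMr); others use offset 1 (local-only
#' numbering).
#'
#' @param label optional filter name; if missing, the whole named list is
#'   returned.
#' @return A [FilterSequence-class] or a named list of them.
#' @examples
#' builtinFilters("CavMr")
#' names(builtinFilters())
#' @export
builtinFilters <- function(label) {
  fs <- list(
    "CavMr"      = filterSequence("TLEGWVD", 183, "CavMr"),
    "CavMr-D7M"  = filterSequence("TLEGWVM", 183, "CavMr-D7M"),
    "NavPp"      = filterSequence("TLEDWTD", 1, "NavPp"),
    "NavPp-T6S"  = filterSequence("TLEDWSD", 1, "NavPp-T6S"),
    "NavPp-T6A"  = filterSequence("TLEDWAD", 1, "NavPp-T6A"),
    "CavAb"      = filterSequence("TLDDWSD", 1, "CavAb"),
    "NaChBac-CaMut" = filterSequence("TLDDWAD", 1, "NaChBac-CaMut"),
    "Bacillus-Nav"  = filterSequence("TLESWAS", 1, "Bacillus-Nav"),
    "NsvBa"      = filterSequence("TLDSWGS", 1, "NsvBa"),
    "CatSper3"   = filterSequence("TVDGWTD", 1, "CatSper3"),
    "CatSper4"   = filterSequence("TQDGWVD", 1, "CatSper4"))
  if (missing(label)) return(fs)
  if (!label %in% names(fs))
    stop("unknown filter label '", label, "'. Available: ",
         paste(names(fs), collapse = ", "))
  fs[[label]]
}

#' Extract filter windows from a FASTA file of parent sequences
#'
#' Reads protein sequences with [Biostrings::readAAStringSet] and extracts a
#' 7-residue filter window starting at the given parent offset for each
#' sequence.
#'
#' @param path FASTA file of parent protein sequences.
#' @param offset parent index of filter position 1; recycled across
#'   sequences.
#' @return list of [FilterSequence-class], named by FASTA record.
#' @export
readFilterFasta <- function(path, offset) {
  seqs <- Biostrings::readAAStringSet(path)
  offset <- rep_len(as.integer(offset), length(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    s <- as.character(Biostrings::subseq(seqs[[i]], offset[i],
                                         offset[i] + 6L))
    filterSequence(s, offset[i], names(seqs)[i])
  })
  names(out) <- names(seqs)
  out
}

#' Export a frequency matrix as CSV
#'
#' @param fm matrix from [frequencyMatrix()].
#' @param path output CSV file.
#' @return invisibly, the path.
#' @export
writeFrequencyMatrixCsv <- function(fm, path) {
  utils::write.csv(as.data.frame(fm), path, row.names = TRUE)
  invisible(path)
}
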