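# Alignment input, validation and the codon coordinate frame.

#' Construct a SampleAlignment from a character matrix
#'
#' @param mat character matrix of single characters (rows = samples); a
#'   character vector of equal-length strings is also accepted. Lower-case
#'   bases are upcased.
#' @param speciesOf named character vector mapping each sample label to its
#'   species.
#' @param roles named character vector mapping each species to
#'   `"ingroup_population"` or `"outgroup"`.
#' @return a validated [SampleAlignment-class]
#' @export
sampleAlignment <- function(mat, speciesOf, roles) {
  if (is.character(mat) && is.null(dim(mat))) {
    labs <- names(mat)
    w <- unique(nchar(mat))
    if (length(w) != 1L)
      stop("sequences have unequal lengths")
    mat <- do.call(rbind, strsplit(mat, ""))
    rownames(mat) <- labs
  }
  mat[] <- toupper(mat)
  new("SampleAlignment", matrix = mat, speciesOf = speciesOf, roles = roles)
}

#' Read a multi-FASTA alignment
#'
#' Reads an aligned FASTA file, validates rectangularity and alphabet, and
#' attaches species labels and roles. Row order is preserved from the file;
#' lower-case bases are accepted and upcased.
#'
#' @param fastaPath path to an aligned FASTA file.
#' @param speciesMap named character vector, sample label -> species; every
#'   record id in the file must be present.
#' @param roles named character vector, species -> role
#'   (`"ingroup_population"` or `"outgroup"`).
#' @return a [SampleAlignment-class]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), fa)
#' aln <- readAlignment(fa, c(a = "sp1", b = "sp1"),
#'                      c(sp1 = "ingroup_population"))
#' nSamples(aln)
#' @export
readAlignment <- function(fastaPath, speciesMap, roles) {
  if (!file.exists(fastaPath)) stop("no such file: ", fastaPath)
  recs <- Biostrings::readBStringSet(fastaPath)
  labs <- sub("\\s.*$", "", names(recs))
  missing <- setdiff(labs, names(speciesMap))
  if (length(missing))
    stop("records absent from speciesMap: ", paste(missing, collapse = ", "))
  seqs <- toupper(as.character(recs))
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    off <- labs[w != w[1]][1]
    stop("ragged alignment: record '", off, "' has length ",
         w[labs == off][1], " (expected ", w[1], ")")
  }
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- labs
  bad <- which(!mat %in% ALN_ALPHABET)
  if (length(bad)) {
    col <- ceiling(bad[1] / nrow(mat))
    stop("invalid character '", mat[bad[1]], "' at alignment column ", col)
  }
  sampleAlignment(mat, speciesMap[labs], roles)
}

#' Write a SampleAlignment as FASTA
#'
#' @param aln a [SampleAlignment-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeAlignment <- function(aln, path) {
  m <- alnMatrix(aln)
  out <- character(2L * nrow(m))
  out[c(TRUE, FALSE)] <- paste0(">", rownames(m))
  out[c(FALSE, TRUE)] <- apply(m, 1L, paste, collapse = "")
  writeLines(out, path)
  invisible(path)
}

#' @rdname SampleAlignment-class
#' @export
setMethod("alnMatrix", "SampleAlignment", function(x) x@matrix)

#' @rdname SampleAlignment-class
#' @export
setMethod("sampleLabels", "SampleAlignment", function(x) rownames(x@matrix))

#' @rdname SampleAlignment-class
#' @export
setMethod("speciesOf", "SampleAlignment",
          function(x) x@speciesOf[rownames(x@matrix)])

#' @rdname SampleAlignment-class
#' @export
setMethod("speciesRoles", "SampleAlignment", function(x) x@roles)

#' @rdname SampleAlignment-class
#' @export
setMethod("nSamples", "SampleAlignment", function(x) nrow(x@matrix))

#' @rdname SampleAlignment-class
#' @export
setMethod("alignmentWidth", "SampleAlignment", function(x) ncol(x@matrix))

setMethod("show", "SampleAlignment", function(object) {
  sp <- table(speciesOf(object))
  cat("SampleAlignment:", nSamples(object), "samples x",
      alignmentWidth(object), "columns\n")
  for (s in names(sp))
    cat("  ", s, ": ", sp[[s]], " sample(s), ",
        speciesRoles(object)[[s]], "\n", sep = "")
})

#' Rows belonging to a species (or role)
#'
#' @param aln a [SampleAlignment-class]
#' @param species character vector of species names; if `NULL`, selects by
#'   `role`.
#' @param role used when `species` is `NULL`: `"ingroup_population"`,
#'   `"outgroup"`, or `NULL` for all rows.
#' @return integer row indices into `alnMatrix(aln)`
#' @export
speciesRows <- function(aln, species = NULL, role = NULL) {
  sp <- speciesOf(aln)
  if (!is.null(species)) return(which(sp %in% species))
  if (is.null(role)) return(seq_along(sp))
  which(speciesRoles(aln)[sp] == role)
}

#' Build a RegionAnnotation
#'
#' @param start,end integer vectors of 0-based half-open segment bounds.
#' @param kind character vector, `"exon"` or `"intron"` per segment.
#' @param phase integer vector: for exons, the position-in-codon (0/1/2) of
#'   the segment's first column; `NA` for introns. Defaults chain phases
#'   from 0 across exons assuming the first exon starts a codon.
#' @return a [RegionAnnotation-class]
#' @export
regionAnnotation <- function(start, end, kind, phase = NULL) {
  if (is.null(phase)) {
    phase <- rep(NA_integer_, length(start))
    acc <- 0L
    for (i in seq_along(start)) {
      if (kind[i] == "exon") {
        phase[i] <- acc %% 3L
        acc <- acc + (end[i] - start[i])
      }
    }
  }
  new("RegionAnnotation",
      segments = data.frame(start = as.integer(start), end = as.integer(end),
                            kind = kind, phase = as.integer(phase)))
}

#' Read a BED-like region annotation TSV
#'
#' Expects columns `start`, `end` (0-based half-open), `kind` and optionally
#' `phase`.
#'
#' @param path TSV file path
#' @return a [RegionAnnotation-class]
#' @export
readRegionAnnotation <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  regionAnnotation(d$start, d$end, d$kind,
                   if ("phase" %in% names(d)) d$phase else NULL)
}

#' @rdname RegionAnnotation-class
#' @param x a `RegionAnnotation`
#' @export
regionSegments <- function(x) x@segments

setMethod("show", "RegionAnnotation", function(object) {
  s <- object@segments
  cat("RegionAnnotation:", nrow(s), "segments,",
      sum(s$end - s$start), "columns\n")
  # 1-based inclusive for human eyes
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s %d..%d%s\n", s$kind[i], s$start[i] + 1L, s$end[i],
                if (s$kind[i] == "exon") paste0(" (phase ", s$phase[i], ")")
                else ""))
})

#' Alignment columns covered by exon / intron segments
#'
#' @param ann a [RegionAnnotation-class]
#' @return integer vector of 1-based alignment columns
#' @export
exonColumns <- function(ann) {
  s <- regionSegments(ann)
  s <- s[s$kind == "exon", , drop = FALSE]
  unlist(lapply(seq_len(nrow(s)),
                function(i) seq.int(s$start[i] + 1L, s$end[i])),
         use.names = FALSE)
}

#' @rdname exonColumns
#' @export
intronColumns <- function(ann) {
  s <- regionSegments(ann)
  s <- s[s$kind == "intron", , drop = FALSE]
  if (!nrow(s)) return(integer())
  unlist(lapply(seq_len(nrow(s)),
                function(i) seq.int(s$start[i] + 1L, s$end[i])),
         use.names = FALSE)
}

#' Check that coding regions stay in frame
#'
#' Diagnostic check of the alignment's coding frame: for every sequence,
#' every run of gap characters inside the concatenated exons must have a
#' length that is a multiple of three (a clean codon insertion/deletion),
#' and the ungapped exonic length must be a multiple of three.
#'
#' @param aln a [SampleAlignment-class]
#' @param ann a [RegionAnnotation-class] within alignment bounds
#' @return a list with elements `pass` (logical), `indels` (data.frame per
#'   exonic gap run: `label`, `startColumn` and `endColumn` (1-based
#'   inclusive, alignment coordinates), `length`, `codonMultiple`) and
#'   `frameErrors` (labels whose ungapped exon length is not a multiple
#'   of 3).
#' @export
validateFrame <- function(aln, ann) {
  s <- regionSegments(ann)
  if (nrow(s) && max(s$end) > alignmentWidth(aln))
    stop("annotation exceeds alignment bounds")
  cols <- exonColumns(ann)
  m <- alnMatrix(aln)[, cols, drop = FALSE]
  indels <- list()
  frameErrors <- character()
  for (i in seq_len(nrow(m))) {
    gap <- m[i, ] == "-"
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      indels[[length(indels) + 1L]] <- data.frame(
        label = rownames(m)[i],
        startColumn = cols[starts[j]], endColumn = cols[ends[j]],
        length = r$lengths[j],
        codonMultiple = r$lengths[j] %% 3L == 0L)
    }
    if (sum(!gap) %% 3L != 0L)
      frameErrors <- c(frameErrors, rownames(m)[i])
  }
  indels <- if (length(indels)) do.call(rbind, indels) else
    data.frame(label = character(), startColumn = integer(),
               endColumn = integer(), length = integer(),
               codonMultiple = logical())
  list(pass = all(indels$codonMultiple) && !length(frameErrors),
       indels = indels, frameErrors = frameErrors)
}

#' Map exon alignment columns to codon coordinates
#'
#' Assigns each exon column a codon index and a position-in-codon, walking
#' the concatenated exons in order and honouring the first exon's phase.
#' Intron columns are unmapped. Codons truncated at the region boundaries
#' (from a non-zero leading phase or a trailing partial codon) are flagged
#' `complete = FALSE` and skipped by codon-level analyses.
#'
#' @param ann a [RegionAnnotation-class]
#' @return data.frame with `column` (1-based alignment column), `codon`
#'   (0-based codon index), `pos` (0/1/2), `complete` (logical)
#' @export
buildCodonMap <- function(ann) {
  s <- regionSegments(ann)
  ex <- s[s$kind == "exon", , drop = FALSE]
  if (!nrow(ex)) stop("annotation contains no exons")
  cols <- exonColumns(ann)
  off <- ex$phase[1]
  # phases must chain: each exon's phase equals the running codon position
  acc <- off
  for (i in seq_len(nrow(ex))) {
    if (ex$phase[i] != acc %% 3L)
      stop("frame inconsistency: exon ", i, " has phase ", ex$phase[i],
           " but chaining implies ", acc %% 3L)
    acc <- acc + (ex$end[i] - ex$start[i])
  }
  k <- seq_along(cols) - 1L + off
  map <- data.frame(column = cols, codon = k %/% 3L, pos = k %% 3L)
  sizes <- table(map$codon)
  map$complete <- map$codon %in% as.integer(names(sizes)[sizes == 3L])
  map
}
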