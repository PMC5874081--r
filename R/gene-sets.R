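#' Normalize gene identifiers
#'
#' Gene IDs are matched at the locus level across datasets from different
#' labs, so identifiers are uppercased and any transcript suffix after the
#' first \code{"."} is stripped (\code{"At1g01010.2"} becomes
#' \code{"AT1G01010"}).
#'
#' @param ids character vector of raw gene identifiers.
#' @return Character vector of normalized IDs (duplicates not removed).
#' @examples
#' normalizeGeneIds(c("at1g01010", "AT3G52250.1"))
#' @export
normalizeGeneIds <- function(ids) {
  toupper(sub("\\..*$", "", trimws(as.character(ids))))
}

#' Read gene lists from plain, TSV or GMT files
#'
#' \describe{
#'   \item{plain}{one gene ID per line; \code{"#"} starts a comment;
#'     members get direction +1.}
#'   \item{tsv}{header row required, with a \code{gene_id} column and any
#'     of \code{log2fc}, \code{padj}, \code{direction}. Direction is taken
#'     from the \code{direction} column when present, otherwise from
#'     \code{sign(log2fc)} (0 is kept as "unassigned" and only rejected if
#'     it survives \code{\link{filterDEGs}}), otherwise +1.}
#'   \item{gmt}{standard tab-separated name, description, member IDs; one
#'     \linkS4class{SignedGeneSet} per record, all directions +1.}
#' }
#'
#' A malformed row raises an error naming its line number; a gene appearing
#' twice in one file with conflicting directions is an error.
#'
#' @param path file to read.
#' @param format one of \code{"plain"}, \code{"tsv"}, \code{"gmt"}.
#' @param label set label for plain/tsv input (defaults to the file name).
#' @return A \linkS4class{SignedGeneSet} for plain/tsv; a list of them
#'   for gmt.
#' @seealso \code{\link{writeGeneList}} for the inverse operation.
#' @export
readGeneList <- function(path, format = c("plain", "tsv", "gmt"),
                         label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label))
    label <- sub("\\.[A-Za-z]+$", "", basename(path))
  switch(format,
         plain = .readPlain(path, label),
         tsv = .readTsv(path, label),
         gmt = .readGmt(path))
}

.readPlain <- function(path, label) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  ids <- lines[nzchar(lines)]
  if (any(grepl("[[:space:]]", ids))) {
    bad <- which(nzchar(lines))[grepl("[[:space:]]", ids)][1L]
    stop("malformed row at line ", bad, " of ", path,
         ": plain format takes one ID per line")
  }
  signedGeneSet(ids, direction = 1L, label = label)
}

.readTsv <- function(path, label) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character")
  if (!"gene_id" %in% names(tab))
    stop("TSV ", path, " lacks the required gene_id column")
  n <- nrow(tab)
  if (n == 0L)
    return(signedGeneSet(character(0), integer(0), label = label))
  lineOf <- function(i) i + 1L  # header occupies line 1
  bad <- which(is.na(tab$gene_id) | !nzchar(trimws(tab$gene_id)))
  if (length(bad))
    stop("malformed row at line ", lineOf(bad[1L]), " of ", path,
         ": missing gene_id")
  numCol <- function(colname) {
    if (!colname %in% names(tab)) return(numeric(0))
    v <- suppressWarnings(as.numeric(tab[[colname]]))
    bad <- which(is.na(v) & nzchar(trimws(tab[[colname]])))
    if (length(bad))
      stop("malformed row at line ", lineOf(bad[1L]), " of ", path,
           ": non-numeric ", colname)
    v
  }
  log2fc <- numCol("log2fc")
  padj <- numCol("padj")
  if ("direction" %in% names(tab)) {
    direction <- suppressWarnings(as.integer(tab$direction))
    if (anyNA(direction) || !all(direction %in% c(-1L, 0L, 1L))) {
      bad <- which(is.na(direction) | !direction %in% c(-1L, 0L, 1L))
      stop("malformed row at line ", lineOf(bad[1L]), " of ", path,
           ": direction must be -1, 0 or 1")
    }
  } else if (length(log2fc)) {
    direction <- as.integer(sign(log2fc))
  } else {
    direction <- rep(1L, n)
  }
  signedGeneSet(tab$gene_id, direction = direction, log2fc = log2fc,
                padj = padj, label = label)
}

.readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("malformed row at line ", i, " of ", path,
           ": GMT needs name, description and at least one member")
    signedGeneSet(fields[-(1:2)], direction = 1L, label = fields[1L])
  })
  names(sets) <- vapply(sets, geneSetLabel, character(1))
  sets
}

#' Write gene lists to plain, TSV or GMT files
#'
#' The TSV form writes \code{gene_id} and \code{direction}, plus
#' \code{log2fc}/\code{padj} when the set carries them, and round-trips
#' through \code{\link{readGeneList}}. GMT writes one record per set.
#' Plain writes IDs only (directions are not representable).
#'
#' @param sets a \linkS4class{SignedGeneSet} or list of them (gmt accepts
#'   several; plain/tsv exactly one).
#' @param path output file.
#' @param format one of \code{"plain"}, \code{"tsv"}, \code{"gmt"}.
#' @return \code{path}, invisibly.
#' @export
writeGeneList <- function(sets, path, format = c("plain", "tsv", "gmt")) {
  format <- match.arg(format)
  if (is(sets, "SignedGeneSet")) sets <- list(sets)
  stopifnot(all(vapply(sets, is, logical(1), "SignedGeneSet")))
  if (format != "gmt" && length(sets) != 1L)
    stop("plain/tsv output takes exactly one set; use gmt for several")
  if (format == "plain") {
    writeLines(geneIds(sets[[1L]]), path)
  } else if (format == "tsv") {
    s <- sets[[1L]]
    tab <- data.frame(gene_id = s@ids, direction = s@direction)
    if (length(s@log2fc)) tab$log2fc <- s@log2fc
    if (length(s@padj)) tab$padj <- s@padj
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- vapply(sets, function(s) {
      paste(c(s@label, "na", s@ids), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Apply the DEG significance filter
#'
#' Keeps exactly the members with \code{padj < alpha} (strict inequality)
#' and assigns each survivor the direction \code{sign(log2fc)}. A survivor
#' with a log2 fold change of exactly zero has no defined direction and is
#' an error.
#'
#' @param x a \linkS4class{SignedGeneSet} in which every member carries a
#'   \code{padj} value.
#' @param alpha significance threshold; default 0.05.
#' @return A filtered \linkS4class{SignedGeneSet}.
#' @examples
#' s <- signedGeneSet(c("g1", "g2"), log2fc = c(2, -1.5),
#'                    padj = c(0.01, 0.2))
#' length(filterDEGs(s))  # 1
#' @export
filterDEGs <- function(x, alpha = 0.05) {
  stopifnot(is(x, "SignedGeneSet"))
  if (length(x@padj) != length(x@ids))
    stop("filterDEGs requires padj for every member of \"", x@label, "\"")
  keep <- !is.na(x@padj) & x@padj < alpha
  log2fc <- if (length(x@log2fc)) x@log2fc[keep] else numeric(0)
  direction <- if (length(log2fc)) as.integer(sign(log2fc))
               else x@direction[keep]
  zero <- which(direction == 0L)
  if (length(zero))
    stop("gene ", x@ids[keep][zero[1L]],
         " passes the padj filter but has log2fc == 0: direction undefined")
  signedGeneSet(x@ids[keep], direction = direction, log2fc = log2fc,
                padj = x@padj[keep], label = x@label)
}

#' Merge signed gene sets, keeping direction-consistent genes
#'
#' Takes the union of the member genes across datasets, excluding any gene
#' observed with both +1 and -1 in different sets; a surviving gene keeps
#' its unanimous direction. Genes absent from a dataset are treated as not
#' measured, never as a conflict. The result is invariant to the order of
#' the input list. The alternative \code{mode = "intersection"} keeps only
#' genes measured in every set (still excluding conflicts).
#'
#' @param sets non-empty list of \linkS4class{SignedGeneSet}s (all
#'   directions must be +/-1).
#' @param mode \code{"union"} (default) or \code{"intersection"}.
#' @param label label for the merged set.
#' @return A \linkS4class{SignedGeneSet}.
#' @examples
#' a <- signedGeneSet(c("g1", "g2"), c(1L, -1L), label = "a")
#' b <- signedGeneSet(c("g1", "g2"), c(1L, 1L), label = "b")
#' geneIds(mergeDirectionConsistent(list(a, b)))  # "G1" only
#' @export
mergeDirectionConsistent <- function(sets, mode = c("union", "intersection"),
                                     label = "merged") {
  mode <- match.arg(mode)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, is, logical(1), "SignedGeneSet")))
  dirs <- lapply(sets, geneDirections)
  if (any(unlist(dirs, use.names = FALSE) == 0L))
    stop("all members must carry a +/-1 direction before merging")
  allIds <- unlist(lapply(dirs, names), use.names = FALSE)
  ids <- unique(allIds)
  dmat <- vapply(dirs, function(d) d[ids], numeric(length(ids)))
  dmat <- matrix(dmat, nrow = length(ids))
  hasUp <- rowSums(dmat == 1L, na.rm = TRUE) > 0L
  hasDn <- rowSums(dmat == -1L, na.rm = TRUE) > 0L
  keep <- !(hasUp & hasDn)
  if (mode == "intersection")
    keep <- keep & rowSums(!is.na(dmat)) == length(sets)
  ids <- ids[keep]
  direction <- ifelse(hasUp[keep], 1L, -1L)
  signedGeneSet(ids, direction = as.integer(direction), label = label)
}

#' @rdname restrictToUniverse
setMethod("restrictToUniverse", signature("SignedGeneSet", "GeneUniverse"),
          function(x, universe) {
  keep <- x@ids %in% universe@ids
  dropped <- sum(!keep)
  if (dropped)
    message(dropped, " of ", length(x@ids), " genes in \"", x@label,
            "\" are outside the universe and were dropped")
  if (!any(keep) && length(x@ids))
    warning("set \"", x@label, "\" has no members inside the universe")
  signedGeneSet(x@ids[keep], direction = x@direction[keep],
                log2fc = if (length(x@log2fc)) x@log2fc[keep] else numeric(0),
                padj = if (length(x@padj)) x@padj[keep] else numeric(0),
                label = x@label)
})

#' @rdname restrictToUniverse
setMethod("restrictToUniverse", signature("AnnotationTrack", "GeneUniverse"),
          function(x, universe) {
  keep <- x@ids %in% universe@ids
  dropped <- sum(!keep)
  if (dropped)
    message(dropped, " of ", length(x@ids), " genes in track \"", x@label,
            "\" are outside the universe and were dropped")
  if (!any(keep) && length(x@ids))
    warning("track \"", x@label, "\" has no members inside the universe")
  annotationTrack(x@label, x@ids[keep], universe)
})
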