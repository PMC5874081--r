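#' Configuration for the synthetic-data generators
#'
#' Bundles and validates every knob of the seeded generators. The
#' defaults describe the study conditions the package is designed around:
#' a universe of 27416 genes (a stand-in for the TAIR10 protein-coding
#' count; the analysis that motivated the package never states its N),
#' a 4081-gene high-H2A.Z track and a 1984-gene H3K9ac track.
#'
#' @param universeSize number of genes in the synthetic universe.
#' @param tracks list of track specs, each a list with \code{label},
#'   \code{size}, and optionally \code{overlapWith} (label of an earlier
#'   track) and \code{overlap} (exact member count shared with it).
#' @param degLists list of DEG-list specs, each a list with \code{label},
#'   \code{size}, \code{theta} (enrichment odds multiplier for members of
#'   \code{track}; 1 = no planted enrichment), \code{track} (target track
#'   label, or NA), and optionally \code{upFraction} (probability the
#'   latent sign of a gene is +1; default 0.5).
#' @param rho probability that a DEG list copies a gene's latent
#'   direction rather than flipping it; rho = 1 gives perfectly
#'   concordant lists, rho = 0.5 gives independent signs.
#' @param phenotype list with \code{levelsA}, \code{levelsB} (factor
#'   level names), \code{n} (observations per cell), \code{mu} (grand
#'   mean, mm scale), \code{effectA}, \code{effectB} (additive effects of
#'   the last level of each factor), \code{betaInt} (interaction effect
#'   added to the last-by-last cell) and \code{sigma} (Gaussian noise SD).
#' @param seed integer master seed; each generator consumes a fixed
#'   sub-seed offset from it (universe +0, tracks +1, DEG lists +2,
#'   phenotypes +3) so generated objects are pure functions of
#'   (config, seed).
#' @return A validated list with class \code{"GeneratorConfig"}.
#' @examples
#' cfg <- generatorConfig(universeSize = 1000,
#'                        tracks = list(list(label = "t1", size = 100)))
#' @export
generatorConfig <- function(universeSize = 27416L,
                            tracks = list(
                              list(label = "high_H2A.Z", size = 4081L),
                              list(label = "H3K9ac", size = 1984L)),
                            degLists = list(),
                            rho = 1,
                            phenotype = list(),
                            seed = 1L) {
  universeSize <- as.integer(universeSize)
  stopifnot(universeSize >= 1L, rho >= 0, rho <= 1)
  for (tr in tracks) {
    stopifnot(!is.null(tr$label), !is.null(tr$size))
    if (tr$size > universeSize)
      stop("track \"", tr$label, "\" larger than the universe")
  }
  for (dl in degLists) {
    stopifnot(!is.null(dl$label), !is.null(dl$size))
    if (dl$size > universeSize)
      stop("DEG list \"", dl$label, "\" larger than the universe")
    theta <- if (is.null(dl$theta)) 1 else dl$theta
    if (theta < 0) stop("theta must be >= 0")
  }
  defaults <- list(levelsA = c("Col-0", "pwr-2"),
                   levelsB = c("23C", "27C"),
                   n = 15L, mu = 5, effectA = -1, effectB = 2,
                   betaInt = -1.5, sigma = 0.5)
  phenotype <- utils::modifyList(defaults, phenotype)
  stopifnot(phenotype$sigma >= 0, phenotype$n >= 1L,
            length(phenotype$levelsA) >= 2L,
            length(phenotype$levelsB) >= 2L)
  structure(list(universeSize = universeSize, tracks = tracks,
                 degLists = degLists, rho = rho, phenotype = phenotype,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Generate a synthetic gene universe
#'
#' Produces AGI-style locus identifiers (ATxGnnnnn over five
#' chromosomes). The universe is a deterministic function of its size, so
#' the same config always yields the same IDs.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @return A \linkS4class{GeneUniverse} of \code{cfg$universeSize} genes.
#' @export
generateUniverse <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  i <- seq_len(cfg$universeSize)
  chr <- (i - 1L) %% 5L + 1L
  pos <- ((i - 1L) %/% 5L + 1L) * 10L
  geneUniverse(sprintf("AT%dG%05d", chr, pos))
}

#' Generate annotation tracks with controlled pairwise overlap
#'
#' Tracks are sampled without replacement from the universe, in the order
#' given. A track spec may pin its overlap with an earlier track
#' (\code{overlapWith}/\code{overlap}): exactly \code{overlap} members
#' are drawn from the reference track and the rest from outside it, which
#' is how fixtures such as "850 of the 1984 H3K9ac genes are high-H2A.Z"
#' are constructed. An infeasible request (overlap larger than either
#' track, or remainder larger than the complement) is an error.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param universe the \linkS4class{GeneUniverse} to sample from.
#' @return Named list of \linkS4class{AnnotationTrack}s.
#' @export
generateTracks <- function(cfg, universe) {
  stopifnot(inherits(cfg, "GeneratorConfig"), is(universe, "GeneUniverse"))
  ids <- geneIds(universe)
  N <- length(ids)
  withr::with_seed(cfg$seed + 1L, {
    out <- list()
    for (tr in cfg$tracks) {
      size <- as.integer(tr$size)
      if (!is.null(tr$overlapWith)) {
        ref <- out[[tr$overlapWith]]
        if (is.null(ref))
          stop("overlapWith refers to unknown track \"",
               tr$overlapWith, "\"")
        ov <- as.integer(tr$overlap)
        inside <- geneIds(ref)
        outside <- setdiff(ids, inside)
        if (ov > min(size, length(inside)) || size - ov > length(outside))
          stop("requested overlap ", ov, " between \"", tr$label,
               "\" and \"", tr$overlapWith, "\" is infeasible")
        members <- c(sample(inside, ov),
                     sample(outside, size - ov))
      } else {
        members <- sample(ids, size)
      }
      out[[tr$label]] <- annotationTrack(tr$label, members, universe)
    }
    out
  })
}

#' Generate signed DEG lists with planted enrichment and concordance
#'
#' Implements the planted-enrichment model: each gene's odds of inclusion
#' in a DEG list are multiplied by \code{theta} if it belongs to the
#' list's target track, and the list is drawn by weighted sampling
#' without replacement (iterative draw-and-remove, so the list size is
#' exact, as in real DEG lists). \code{theta = 1} is the uniform null;
#' \code{theta = Inf} draws entirely from the track. Directions follow a
#' latent per-gene sign, drawn once per config: the first list copies the
#' latent signs exactly (it plays the role of the reference dataset) and
#' every later list copies a member's latent sign with probability
#' \code{rho}, flipping it otherwise, so the expected cross-list sign
#' agreement with the reference is exactly \code{rho} — concordant
#' classes dominate the directional partition when \code{rho > 0.5} and
#' discordant classes when \code{rho < 0.5}.
#'
#' @param cfg a \code{\link{generatorConfig}} with non-empty
#'   \code{degLists}.
#' @param universe the \linkS4class{GeneUniverse}.
#' @param tracks named list of \linkS4class{AnnotationTrack}s (as from
#'   \code{\link{generateTracks}}).
#' @return Named list of \linkS4class{SignedGeneSet}s.
#' @export
generateDegLists <- function(cfg, universe, tracks = list()) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  ids <- geneIds(universe)
  N <- length(ids)
  withr::with_seed(cfg$seed + 2L, {
    upFracs <- vapply(cfg$degLists, function(dl)
      if (is.null(dl$upFraction)) 0.5 else dl$upFraction, numeric(1))
    upFrac <- if (length(upFracs)) upFracs[1L] else 0.5
    latent <- sample(c(1L, -1L), N, replace = TRUE,
                     prob = c(upFrac, 1 - upFrac))
    names(latent) <- ids
    out <- list()
    for (dl in cfg$degLists) {
      size <- as.integer(dl$size)
      theta <- if (is.null(dl$theta)) 1 else dl$theta
      trackLabel <- dl$track
      inTrack <- if (!is.null(trackLabel) && !is.na(trackLabel)) {
        if (is.null(tracks[[trackLabel]]))
          stop("DEG list \"", dl$label, "\" targets unknown track \"",
               trackLabel, "\"")
        ids %in% geneIds(tracks[[trackLabel]])
      } else rep(FALSE, N)
      if (is.infinite(theta)) {
        pool <- ids[inTrack]
        if (size > length(pool))
          stop("theta = Inf but list size exceeds the track size")
        members <- sample(pool, size)
      } else {
        w <- ifelse(inTrack, theta, 1)
        members <- sample(ids, size, prob = w)
      }
      # the first list anchors the latent signs (it is the reference
      # dataset); later lists copy each sign with probability rho
      pFlip <- if (length(out) == 0L) 0 else 1 - cfg$rho
      flip <- rbinom(size, 1L, pFlip) == 1L
      direction <- ifelse(flip, -latent[members], latent[members])
      out[[dl$label]] <- signedGeneSet(members,
                                       direction = as.integer(direction),
                                       label = dl$label)
    }
    out
  })
}

#' Generate a balanced two-factor phenotype table
#'
#' Emulates hypocotyl-length style measurements: a balanced design over
#' the two factors with cell mean
#' mu + effectA (last A level) + effectB (last B level) + betaInt
#' (last-by-last cell only) and independent Gaussian noise of SD sigma.
#' With sigma = 0 and betaInt = b, the balanced 2x2 interaction sum of
#' squares is exactly n b^2 / 4.
#'
#' @param cfg a \code{\link{generatorConfig}}; see its \code{phenotype}
#'   argument for the knobs.
#' @return A phenotype data frame (factor_a, factor_b, replicate, value).
#' @export
generatePhenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  ph <- cfg$phenotype
  la <- ph$levelsA; lb <- ph$levelsB
  grid <- expand.grid(factor_a = la, factor_b = lb,
                      replicate = seq_len(ph$n),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mean0 <- ph$mu +
    ifelse(grid$factor_a == la[length(la)], ph$effectA, 0) +
    ifelse(grid$factor_b == lb[length(lb)], ph$effectB, 0) +
    ifelse(grid$factor_a == la[length(la)] &
             grid$factor_b == lb[length(lb)], ph$betaInt, 0)
  withr::with_seed(cfg$seed + 3L, {
    grid$value <- mean0 + rnorm(nrow(grid), 0, ph$sigma)
  })
  grid
}

#' Write every synthetic input to files plus a manifest
#'
#' Emits the same formats the readers consume: a plain universe list,
#' one TSV per DEG list, one GMT holding the annotation tracks, a
#' phenotype TSV, and a YAML manifest recording the config and seed.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
writeSyntheticInputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  u <- generateUniverse(cfg)
  tracks <- generateTracks(cfg, u)
  degs <- generateDegLists(cfg, u, tracks)
  pheno <- generatePhenotypes(cfg)
  paths <- list(universe = file.path(dir, "universe.txt"),
                tracks = file.path(dir, "tracks.gmt"),
                phenotypes = file.path(dir, "phenotypes.tsv"),
                manifest = file.path(dir, "manifest.yaml"))
  writeLines(geneIds(u), paths$universe)
  if (length(tracks)) {
    trackSets <- lapply(tracks, function(t)
      signedGeneSet(geneIds(t), 1L, label = geneSetLabel(t)))
    writeGeneList(trackSets, paths$tracks, format = "gmt")
  }
  for (nm in names(degs)) {
    p <- file.path(dir, paste0("deg_", nm, ".tsv"))
    writeGeneList(degs[[nm]], p, format = "tsv")
    paths[[paste0("deg_", nm)]] <- p
  }
  writePhenotypeTable(pheno, paths$phenotypes)
  manifest <- unclass(cfg)
  manifest$package_version <- as.character(packageVersion("degOverlap"))
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}
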