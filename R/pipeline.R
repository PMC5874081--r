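#' Read a pipeline run configuration
#'
#' The run configuration is a YAML file with the blocks
#' \describe{
#'   \item{seed}{master seed for every source of randomness.}
#'   \item{alpha}{significance threshold, default 0.05.}
#'   \item{generator}{optional synthetic-input spec mirroring
#'     \code{\link{generatorConfig}} (keys universe_size, tracks,
#'     deg_lists, rho, phenotype).}
#'   \item{inputs}{optional file inputs: \code{universe} (plain list),
#'     \code{tracks_gmt}, \code{deg_lists} (list of \{label, path,
#'     format, filter_alpha\}), \code{phenotypes} (TSV).}
#'   \item{comparisons}{list of \{a, b\} label pairs to overlap-test;
#'     \code{b} may name a DEG list or a track.}
#'   \item{stratified}{list of \{a, tracks, intersect\}: overlap of
#'     \code{a} against each track, or against their intersection when
#'     \code{intersect} is true.}
#'   \item{null_calibration}{\{K, size_range\} for the Monte Carlo null; omit to skip
#'     calibration.}
#'   \item{merge}{optional list of \{label, sets, mode\} building
#'     direction-consistent merged lists before comparisons run.}
#' }
#'
#' @param path YAML file.
#' @return The configuration as a named list (class \code{"RunConfig"}).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "RunConfig", configDir = dirname(path))
}

.cfgPath <- function(cfg, p) {
  dir <- attr(cfg, "configDir")
  if (!is.null(dir) && !file.exists(p) && file.exists(file.path(dir, p)))
    file.path(dir, p) else p
}

.generatorFromConfig <- function(cfg) {
  g <- cfg$generator
  snake <- function(x, key, default) if (is.null(x[[key]])) default else x[[key]]
  tracks <- lapply(snake(g, "tracks", list()), function(tr)
    list(label = tr$label, size = tr$size,
         overlapWith = tr$overlap_with, overlap = tr$overlap))
  degs <- lapply(snake(g, "deg_lists", list()), function(dl)
    list(label = dl$label, size = dl$size,
         theta = snake(dl, "theta", 1), track = dl$track,
         upFraction = snake(dl, "up_fraction", 0.5)))
  generatorConfig(universeSize = snake(g, "universe_size", 27416L),
                  tracks = tracks, degLists = degs,
                  rho = snake(g, "rho", 1),
                  phenotype = snake(g, "phenotype", list()),
                  seed = as.integer(if (is.null(cfg$seed)) 1L else cfg$seed))
}

.loadInputs <- function(cfg) {
  universe <- NULL; tracks <- list(); degs <- list(); pheno <- NULL
  if (!is.null(cfg$generator)) {
    gcfg <- .generatorFromConfig(cfg)
    universe <- generateUniverse(gcfg)
    tracks <- generateTracks(gcfg, universe)
    degs <- generateDegLists(gcfg, universe, tracks)
    if (!is.null(cfg$generator$phenotype) || is.null(cfg$inputs$phenotypes))
      pheno <- generatePhenotypes(gcfg)
  }
  ins <- cfg$inputs
  if (!is.null(ins$universe))
    universe <- geneUniverse(readLines(.cfgPath(cfg, ins$universe)))
  if (!is.null(ins$tracks_gmt)) {
    sets <- readGeneList(.cfgPath(cfg, ins$tracks_gmt), format = "gmt")
    for (s in sets)
      tracks[[geneSetLabel(s)]] <- annotationTrack(
        geneSetLabel(s),
        intersect(geneIds(s), geneIds(universe)), universe)
  }
  for (dl in ins$deg_lists) {
    fmt <- if (is.null(dl$format)) "tsv" else dl$format
    s <- readGeneList(.cfgPath(cfg, dl$path), format = fmt,
                      label = dl$label)
    if (!is.null(dl$filter_alpha)) s <- filterDEGs(s, dl$filter_alpha)
    degs[[geneSetLabel(s)]] <- s
  }
  if (!is.null(ins$phenotypes))
    pheno <- readPhenotypeTable(.cfgPath(cfg, ins$phenotypes))
  if (is.null(universe)) stop("config declares no universe")
  for (m in cfg$merge) {
    mode <- if (is.null(m$mode)) "union" else m$mode
    degs[[m$label]] <- mergeDirectionConsistent(degs[m$sets], mode = mode,
                                                label = m$label)
  }
  list(universe = universe, tracks = tracks, degs = degs, pheno = pheno)
}

#' Dry-run validation of a run configuration
#'
#' Checks the configuration without running the analysis: referenced
#' files exist, comparison labels are declared, list sizes are feasible
#' for the universe, and every loadable gene list is checked for universe
#' coverage (a finding reports the exact fraction outside the universe).
#'
#' @param cfg a \code{"RunConfig"} (see \code{\link{readRunConfig}}) or a
#'   path to one.
#' @return Data frame of findings with columns \code{severity}
#'   (\code{"error"}/\code{"warning"}/\code{"info"}) and \code{message};
#'   zero rows when nothing is wrong.
#' @export
validateRunConfig <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  findings <- data.frame(severity = character(0), message = character(0))
  note <- function(severity, message) {
    rbind(findings, data.frame(severity = severity, message = message))
  }
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1))
    findings <- note("error", "alpha must lie in (0, 1)")
  filesMissing <- FALSE
  for (p in c(cfg$inputs$universe, cfg$inputs$tracks_gmt,
              cfg$inputs$phenotypes,
              vapply(cfg$inputs$deg_lists, `[[`, character(1), "path")))
    if (!file.exists(.cfgPath(cfg, p))) {
      findings <- note("error", paste("missing file:", p))
      filesMissing <- TRUE
    }
  if (filesMissing) return(findings)
  loaded <- tryCatch(.loadInputs(cfg), error = function(e) e)
  if (inherits(loaded, "error"))
    return(note("error", conditionMessage(loaded)))
  labels <- c(names(loaded$degs), names(loaded$tracks))
  for (cmp in cfg$comparisons)
    for (side in c(cmp$a, cmp$b))
      if (!side %in% labels)
        findings <- note("error",
                         paste("comparison references undeclared list:", side))
  for (st in cfg$stratified) {
    if (!st$a %in% names(loaded$degs))
      findings <- note("error",
                       paste("stratified comparison references undeclared list:",
                             st$a))
    for (tr in st$tracks)
      if (!tr %in% names(loaded$tracks))
        findings <- note("error", paste("undeclared track:", tr))
  }
  uIds <- geneIds(loaded$universe)
  for (nm in names(loaded$degs)) {
    s <- loaded$degs[[nm]]
    if (!length(s)) next
    out <- mean(!geneIds(s) %in% uIds)
    if (out > 0)
      findings <- note("warning",
                       sprintf("list \"%s\": %.1f%% of members outside the universe",
                               nm, 100 * out))
  }
  if (!is.null(cfg$null_calibration) &&
      !is.null(cfg$null_calibration$size_range) &&
      max(unlist(cfg$null_calibration$size_range)) > length(loaded$universe))
    findings <- note("error", "null size_range exceeds the universe size")
  findings
}

.writeTsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full overlap meta-analysis pipeline
#'
#' Loads or generates every configured input, runs all pairwise and
#' stratified overlap tests with directional partitions, calibrates the
#' observed overlap p-values against the Monte Carlo null, runs the
#' phenotype interaction ANOVA and reaction-norm summary, and writes a
#' TSV report per stage plus a JSON mirror and a run log. Reruns with the
#' same config and seed produce byte-identical tables. On failure a
#' \code{FAILED} marker file is written next to any partial outputs and
#' the error is re-raised.
#'
#' @param cfg a \code{"RunConfig"} or path to a YAML config.
#' @param outDir output directory (created); defaults to the config's
#'   \code{out_dir} or \code{"degoverlap_run"}.
#' @param seed optional override of the config seed.
#' @return Invisibly, a list with the computed objects (overlaps, null,
#'   nullReport, anova, reactionNorms, paths).
#' @export
runPipeline <- function(cfg, outDir = NULL, seed = NULL) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(outDir))
    outDir <- if (!is.null(cfg$out_dir)) cfg$out_dir else "degoverlap_run"
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character(0)
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    logLines <<- c(logLines, line)
  }
  tryCatch({
    logf("degOverlap %s, seed %d, RNG %s",
         as.character(packageVersion("degOverlap")), cfg$seed, RNGkind()[1L])
    inputs <- .loadInputs(cfg)
    u <- inputs$universe
    logf("universe: %d genes; %d tracks; %d DEG lists",
         length(u), length(inputs$tracks), length(inputs$degs))
    pool <- c(inputs$degs, inputs$tracks)

    results <- list()
    for (cmp in cfg$comparisons) {
      a <- inputs$degs[[cmp$a]]
      b <- pool[[cmp$b]]
      if (is.null(a) || is.null(b))
        stop("comparison references undeclared list: ",
             if (is.null(a)) cmp$a else cmp$b)
      r <- overlapTest(a, b, u)
      logf("overlap %s vs %s: N=%d n_a=%d n_b=%d k=%d p=%.4g",
           cmp$a, cmp$b, r@N, r@nA, r@nB, r@k, r@pUpper)
      results[[length(results) + 1L]] <- r
    }
    for (st in cfg$stratified) {
      a <- inputs$degs[[st$a]]
      strata <- inputs$tracks[unlist(st$tracks)]
      if (isTRUE(st$intersect) && length(strata) > 1L)
        strata <- list(Reduce(intersectTracks, strata))
      for (r in stratifiedOverlap(a, strata, u)) {
        logf("stratified %s vs %s: k=%d p=%.4g",
             st$a, r@labelB, r@k, r@pUpper)
        results[[length(results) + 1L]] <- r
      }
    }
    overlapTab <- if (length(results)) overlapResultTable(results) else
      overlapResultTable(list())
    paths <- list(overlaps = file.path(outDir, "overlaps.tsv"))
    provenance <- c(paste("degOverlap", packageVersion("degOverlap")),
                    paste("seed", cfg$seed))
    if (length(results)) {
      .writeTsv(overlapTab, paths$overlaps, provenance)
    } else {
      hdr <- overlapResultTable(list(
        overlapTest(signedGeneSet("X1", label = "x"),
                    signedGeneSet("X1", label = "x"),
                    geneUniverse("X1"))))[0, ]
      .writeTsv(hdr, paths$overlaps, provenance)
    }

    nd <- NULL; nrep <- NULL
    if (!is.null(cfg$null_calibration)) {
      K <- if (is.null(cfg$null_calibration$K)) 100000L else as.integer(cfg$null_calibration$K)
      sr <- if (is.null(cfg$null_calibration$size_range)) c(500L, 2000L)
            else as.integer(unlist(cfg$null_calibration$size_range))
      nd <- simulateNull(u, K = K, sizeRange = sr, seed = cfg$seed)
      logf("null: K=%d, fraction<=0.05 = %.4f", K,
           mean(nullPvalues(nd) <= 0.05))
      observed <- if (length(results))
        data.frame(label = paste(overlapTab$label_a, "vs", overlapTab$label_b),
                   p = overlapTab$p_upper)
      else NULL
      nrep <- nullReport(nd, observed)
      paths$null <- file.path(outDir, "null_distribution.tsv")
      writeNullDistribution(nd, paths$null)
      paths$nullSummary <- .writeTsv(nrep$summary,
                                     file.path(outDir, "null_summary.tsv"),
                                     provenance)
      paths$nullObservations <- .writeTsv(
        nrep$observations, file.path(outDir, "null_observations.tsv"),
        provenance)
    }

    anova <- NULL; norms <- NULL
    if (!is.null(inputs$pheno)) {
      anova <- twoWayAnovaInteraction(inputs$pheno)
      norms <- reactionNormSummary(inputs$pheno)
      logf("phenotype ANOVA: F=%.4g p=%.4g",
           anova@fInteraction, anova@pInteraction)
      anovaTab <- data.frame(term = names(anova@ss), ss = anova@ss,
                             df = anova@df, row.names = NULL)
      anovaTab$F <- c(NA, NA, anova@fInteraction, NA)
      anovaTab$p <- c(NA, NA, anova@pInteraction, NA)
      paths$anova <- .writeTsv(anovaTab,
                               file.path(outDir, "phenotype_anova.tsv"),
                               provenance)
      paths$reactionNorms <- .writeTsv(
        norms, file.path(outDir, "reaction_norms.tsv"), provenance)
    }

    report <- list(seed = cfg$seed, alpha = cfg$alpha,
                   n_comparisons = length(results),
                   overlaps = overlapTab)
    if (!is.null(nrep)) report$null <- nrep
    if (!is.null(anova))
      report$interaction = list(F = anova@fInteraction,
                                p = anova@pInteraction)
    paths$json <- file.path(outDir, "report.json")
    jsonlite::write_json(report, paths$json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE)
    paths$log <- file.path(outDir, "run_log.txt")
    writeLines(logLines, paths$log)
    invisible(list(overlaps = results, null = nd, nullReport = nrep,
                   anova = anova, reactionNorms = norms, paths = paths))
  }, error = function(e) {
    writeLines(c(logLines, paste("FAILED:", conditionMessage(e))),
               file.path(outDir, "FAILED"))
    stop(e)
  })
}
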