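# End-to-end orchestration: load or simulate networks, compute parameters,
# detect and test modules, assemble ARD tables, and write a reproducible
# plain-text report.

#' Build an analysis configuration
#'
#' @param inputs list of `list(name=, adjacency=, classes=)` entries
#'   pointing at CSV files (see [readAnatomicalNetwork()]).
#' @param presets character vector of [presetLimbSpec()] names to
#'   simulate instead of (or besides) file inputs.
#' @param parameterTable path to a Table-1-style parameter TSV; when set,
#'   the run is a pure replay: ARD is computed from the given rows and no
#'   graphs are needed.
#' @param levels which induced levels to analyse: any of `"full"`,
#'   `"skeletal"`, `"muscular"`.
#' @param steps random-walk length for module detection (default 3).
#' @param clusteringMode,sdType numerical conventions for C and H.
#' @param largestComponent analyse largest components of disconnected
#'   (sub)networks instead of failing.
#' @param symmetrize accept asymmetric adjacency input as `max(A, t(A))`.
#' @param seed integer seed for simulated inputs.
#' @return an [AnalysisConfig-class].
#' @export
analysisConfig <- function(inputs = list(), presets = character(0),
                           parameterTable = "", levels = "full",
                           steps = 3L,
                           clusteringMode = c("exclude", "zero"),
                           sdType = c("sample", "population"),
                           largestComponent = FALSE, symmetrize = FALSE,
                           seed = 1L) {
  new("AnalysisConfig", inputs = inputs, presets = presets,
      parameterTable = as.character(parameterTable)[1L],
      levels = levels, steps = as.integer(steps),
      clusteringMode = match.arg(clusteringMode),
      sdType = match.arg(sdType),
      largestComponent = isTRUE(largestComponent),
      symmetrize = isTRUE(symmetrize), seed = as.integer(seed))
}

.levelClasses <- function(level) {
  switch(level,
         full = c("bone", "cartilage", "muscle"),
         skeletal = c("bone", "cartilage"),
         muscular = "muscle",
         .anStop("unknownLevelError", "unknown level '%s'", level))
}

# Re-raise any failure with the pipeline stage prepended, keeping the
# original condition classes so callers can still match on them.
.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("[stage %s] %s", stage, conditionMessage(e)),
      class = unique(c("stageError",
                       setdiff(class(e), c("error", "condition"))))))
  })
}

#' Run a full analysis
#'
#' Executes every stage in order -- load/simulate, validate, slice into
#' levels, parameters, module detection (partition, Q, jackknife SE,
#' per-module rank-sum tests), pairwise ARD -- and returns the assembled
#' [AnalysisReport-class].  A failure in any network aborts the run with
#' an error naming the stage.  Deterministic: the same configuration
#' (including seed) always yields the same report.
#'
#' In replay mode (`parameterTable` set) only the parameter table and its
#' ARD matrix are produced, allowing published parameter rows to be
#' compared without the underlying matrices.
#'
#' @param config an [AnalysisConfig-class].
#' @return an [AnalysisReport-class].
#' @seealso [writeReport()]
#' @export
setMethod("runAnalysis", "AnalysisConfig", function(config) {
  validObject(config)
  meta <- list(
    package = as.character(utils::packageVersion("anatnet")),
    r_version = R.version.string,
    steps = config@steps, clusteringMode = config@clusteringMode,
    sdType = config@sdType, seed = config@seed,
    levels = config@levels,
    ard_formula = "mean over {N,K,D,C,L,H} of |a-b| / pair mean, x 100")

  if (nzchar(config@parameterTable)) {
    params <- .stage("replay", readParameterTable(config@parameterTable))
    ptab <- do.call(rbind, lapply(params, as.data.frame))
    ptab <- cbind(ptab[, "network", drop = FALSE], level = "replay",
                  ptab[, -1L, drop = FALSE])
    rownames(ptab) <- NULL
    ardList <- list(replay = ardMatrix(params))
    return(new("AnalysisReport", parameters = ptab,
               partitions = list(),
               moduleTests = data.frame(), ard = ardList, meta = meta))
  }

  nets <- list()
  for (inp in config@inputs) {
    net <- .stage(sprintf("load:%s", inp$name),
                  readAnatomicalNetwork(inp$adjacency, inp$classes,
                                        name = inp$name,
                                        symmetrize = config@symmetrize))
    nets[[inp$name]] <- net
  }
  for (i in seq_along(config@presets)) {
    pr <- config@presets[i]
    spec <- presetLimbSpec(pr)
    spec@seed <- config@seed + i - 1L
    nets[[pr]] <- .stage(sprintf("simulate:%s", pr),
                         generateLimbNetwork(spec))
  }
  for (nm in names(nets)) {
    bad <- validateNetwork(nets[[nm]])
    if (length(bad))
      .anStop("stageError", "[stage validate:%s] %s", nm,
              paste(bad, collapse = "; "))
  }

  prows <- list(); partitions <- list(); mtests <- list()
  ardList <- list()
  for (lev in config@levels) {
    levParams <- list()
    for (nm in names(nets)) {
      sub <- .stage(sprintf("subnetwork:%s:%s", nm, lev),
                    subNetwork(nets[[nm]], .levelClasses(lev)))
      p <- .stage(sprintf("parameters:%s:%s", nm, lev),
                  networkParameters(
                    sub, lowDegreeMode = config@clusteringMode,
                    sdType = config@sdType,
                    largestComponent = config@largestComponent))
      levParams[[nm]] <- p
      prows[[paste(nm, lev, sep = "|")]] <-
        cbind(data.frame(network = nm, level = lev,
                         stringsAsFactors = FALSE),
              as.data.frame(p)[, -1L])
      part <- .stage(sprintf("modules:%s:%s", nm, lev), {
        tree <- walktrapTree(sub, steps = config@steps)
        scorePartition(sub, bestPartition(tree, sub))
      })
      partitions[[paste(nm, lev, sep = "|")]] <- part
      tt <- .stage(sprintf("moduleTests:%s:%s", nm, lev),
                   moduleTestTable(sub, part))
      mtests[[paste(nm, lev, sep = "|")]] <-
        cbind(data.frame(network = nm, level = lev,
                         stringsAsFactors = FALSE), tt)
    }
    if (length(levParams) >= 2L) {
      pl <- levParams
      for (nm in names(pl)) pl[[nm]]@name <- nm
      ardList[[lev]] <- ardMatrix(pl)
    }
  }
  params <- do.call(rbind, prows)
  rownames(params) <- NULL
  mt <- if (length(mtests)) do.call(rbind, mtests) else data.frame()
  rownames(mt) <- NULL
  new("AnalysisReport", parameters = params, partitions = partitions,
      moduleTests = mt, ard = ardList, meta = meta)
})

setMethod("show", "AnalysisReport", function(object) {
  cat(sprintf(
    "AnalysisReport: %d parameter rows, %d partitions, %d ARD matrices\n",
    nrow(object@parameters), length(object@partitions),
    length(object@ard)))
})

.fmtParams <- function(df) {
  out <- df
  for (col in c("D", "C", "L", "H"))
    out[[col]] <- sprintf("%.3f", df[[col]])
  out
}

#' Write an analysis report to disk
#'
#' Writes `parameters.tsv` (Table-1-like: network, level, N, K, D, C, L,
#' H, with D/C/L/H at 3 decimals), `modules.tsv` (per-module test table),
#' one `partitions/<network>.<level>.csv` per partition (label, module,
#' plus Q and its SE in the header comment), `ard_matrix_<level>.tsv`
#' (1-decimal percentages), and `run_log.txt` (settings, conventions,
#' versions, seed -- no timestamps, so reruns are byte-identical).
#' Refuses to overwrite a non-empty directory unless `force = TRUE`.
#'
#' @param report an [AnalysisReport-class].
#' @param outdir output directory (created if missing).
#' @param force overwrite existing report files.
#' @return invisibly, the character vector of written paths.
#' @export
setMethod("writeReport", "AnalysisReport",
function(report, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !isTRUE(force))
    .anStop("existingOutputError",
            "output directory '%s' is not empty; use force = TRUE", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "partitions"), showWarnings = FALSE)
  written <- character(0)
  wr <- function(df, file, dec3 = FALSE) {
    path <- file.path(outdir, file)
    utils::write.table(if (dec3) .fmtParams(df) else df, path,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
  }
  wr(report@parameters, "parameters.tsv", dec3 = TRUE)
  if (nrow(report@moduleTests)) {
    mt <- report@moduleTests
    mt$p <- sprintf("%.6g", mt$p)
    wr(mt, "modules.tsv")
  }
  for (key in names(report@partitions)) {
    part <- report@partitions[[key]]
    path <- file.path(outdir, "partitions",
                      paste0(gsub("[|]", ".", key), ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# Q=%.6f SE=%.6f", part@q, part@qSE), con)
    utils::write.csv(
      data.frame(label = names(part@membership),
                 module = unname(part@membership)),
      con, row.names = FALSE, quote = FALSE)
    close(con)
    written <- c(written, path)
  }
  for (lev in names(report@ard)) {
    M <- reportRound(report@ard[[lev]], 1L)
    df <- data.frame(network = rownames(M), M, check.names = FALSE)
    wr(df, sprintf("ard_matrix_%s.tsv", lev))
  }
  logPath <- file.path(outdir, "run_log.txt")
  meta <- report@meta
  writeLines(c(
    sprintf("anatnet %s (%s)", meta$package, meta$r_version),
    sprintf("walk steps: %d", meta$steps),
    sprintf("clustering low-degree mode: %s", meta$clusteringMode),
    sprintf("heterogeneity sd convention: %s", meta$sdType),
    sprintf("levels: %s", paste(meta$levels, collapse = ", ")),
    sprintf("seed: %d", meta$seed),
    sprintf("ARD: %s", meta$ard_formula)), logPath)
  written <- c(written, logPath)
  invisible(written)
})
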