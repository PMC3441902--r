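#' @include clustering.R synthetic.R preprocess.R imzml.R
NULL

.md5OfObject <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2L)
    unname(tools::md5sum(f))
}

.defaultConfig <- function() list(
    input = list(type = "synth", preset = "small", path = NULL, seed = 1L),
    preprocess = list(log = TRUE, log_offset = 1, baseline = TRUE, knots = 5L,
                      robust_iterations = 10L, retain = NULL,
                      filter_mode = "snr"),
    transform = list(method = "mnf", bands = 6L, ridge = 0),
    cluster = list(enabled = TRUE, bands = 4L, k = 7L, linkage = "ward"),
    output = list(dir = ".", prefix = "run"))

.mergeConfig <- function(user, defaults) {
    for (nm in names(defaults)) {
        if (is.null(user[[nm]])) {
            user[[nm]] <- defaults[[nm]]
        } else if (is.list(defaults[[nm]])) {
            user[[nm]] <- .mergeConfig(user[[nm]], defaults[[nm]])
        }
    }
    user
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their canonical order — input (or synthesis),
#' log transform, baseline correction, channel pre-filtering, covariance
#' estimation, PCA or MNF transform, hierarchical clustering — and writes
#' band images, the band-score table, the eigenvalue table, cluster
#' outputs and a JSON run manifest recording inputs, the config snapshot,
#' seed, per-stage timings, spot/channel bookkeeping after each filter, an
#' md5 hash of the spectrum covariance, output files and the package
#' version. Deterministic stages re-run bit-identically from the same
#' manifest inputs.
#'
#' Any stage error aborts the run with the stage name and cause, and
#' partial outputs written by this run are removed.
#'
#' @param config a config list, or the path of a YAML file holding one.
#'   Sections (all optional, with defaults): `input` (`type`:
#'   `"synth"`/`"matrix"`/`"imzml"`, `path`, `preset`:
#'   `"small"`/`"tissue-scale"`, `seed`), `preprocess` (`log`,
#'   `log_offset`, `baseline`, `knots`, `robust_iterations`, `retain`,
#'   `filter_mode`), `transform` (`method`, `bands`, `ridge`), `cluster`
#'   (`enabled`, `bands`, `k`, `linkage`), `output` (`dir`, `prefix`).
#' @return the manifest, invisibly (also written as
#'   `<prefix>_manifest.json`).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file does not exist: ", config)
        config <- yaml::read_yaml(config)
    }
    cfg <- .mergeConfig(config, .defaultConfig())
    outDir <- cfg$output$dir
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    prefix <- file.path(outDir, cfg$output$prefix)
    written <- character()
    timings <- list()
    counts <- list()
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(force(expr), error = function(e) {
            unlink(written)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
        timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
        res
    }

    grid <- stage("input", {
        inp <- cfg$input
        if (identical(inp$type, "synth")) {
            if (identical(inp$preset, "tissue-scale")) {
                tissueScaleFixture(seed = inp$seed)
            } else {
                generateGrid(synthConfig(nCols = 20L, nRows = 16L, p = 120L,
                                         q = 3L, seed = inp$seed))$grid
            }
        } else {
            if (is.null(inp$path) || !file.exists(inp$path %||% ""))
                stop("input file does not exist: ",
                     if (is.null(inp$path)) "<missing path>" else inp$path)
            readSpectrumGrid(inp$path, format = inp$type)
        }
    })
    counts$spots <- nSpots(grid)
    counts$channels <- nChannels(grid)
    message("input: ", counts$spots, " spots x ", counts$channels,
            " channels")

    if (isTRUE(cfg$preprocess$log))
        grid <- stage("log", logTransform(grid, cfg$preprocess$log_offset))
    if (isTRUE(cfg$preprocess$baseline))
        grid <- stage("baseline",
                      baselineCorrectGrid(grid, nKnots = cfg$preprocess$knots,
                          robustIterations = cfg$preprocess$robust_iterations))

    retain <- cfg$preprocess$retain
    channels <- stage("prefilter", {
        if (is.null(retain) || retain >= nChannels(grid)) {
            seq_len(nChannels(grid))
        } else {
            mode <- if (identical(cfg$transform$method, "pca") &&
                        identical(cfg$preprocess$filter_mode, "auto"))
                "intensity" else cfg$preprocess$filter_mode
            prefilterGrid(grid, mode = mode, retainK = retain)
        }
    })
    counts$channels_retained <- length(channels)
    message("prefilter: ", counts$channels_retained, " of ",
            nChannels(grid), " channels retained")

    cp <- stage("covariance", covariancePair(grid, channels))
    counts$valid_residual_spots <- cp@nValidResiduals

    bands <- stage("transform", {
        K <- cfg$transform$bands
        if (identical(cfg$transform$method, "pca")) {
            pcaBands(grid, K, channels = channels)
        } else {
            core <- tryCatch(
                .mnfCore(cp@SZ, cp@SN, K, cfg$transform$ridge),
                error = function(e) {
                    warning("noise covariance factorisation failed; ",
                            "retrying with ridge = 1e-8")
                    .mnfCore(cp@SZ, cp@SN, K, ridge = 1e-8)
                })
            new("BandDecomposition", vectors = core$vectors,
                eigenvalues = core$eigenvalues,
                scores = .bandScores(grid, channels, core$vectors),
                method = cfg$transform$method, channels = channels)
        }
    })
    written <- c(written, stage("write-bands", {
        f1 <- writeBands(bands, grid, prefix)
        f2 <- writeEigenvalueTable(bands,
                                   paste0(prefix, "_eigenvalues.csv"))
        c(f1, f2)
    }))

    if (isTRUE(cfg$cluster$enabled)) {
        cl <- stage("cluster",
                    clusterSpots(bands, grid, k = cfg$cluster$k,
                                 nBands = min(cfg$cluster$bands,
                                              length(bandEigenvalues(bands))),
                                 linkage = cfg$cluster$linkage))
        written <- c(written, stage("write-cluster",
                                    writeClusterResult(cl, grid, prefix)))
    }

    manifest <- list(
        package = "imsmnf",
        version = as.character(utils::packageVersion("imsmnf")),
        input = cfg$input[!vapply(cfg$input, is.null, logical(1L))],
        config = cfg[c("preprocess", "transform", "cluster")],
        seed = cfg$input$seed,
        counts = counts,
        timings = timings,
        sz_md5 = .md5OfObject(cp@SZ),
        outputs = as.character(written))
    mf <- paste0(prefix, "_manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest$manifest_path <- mf
    invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
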