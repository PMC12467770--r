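PIPELINE_STAGES <- c("simulate", "balance", "train", "extract",
                     "expressivity", "evaluate", "report")

#' End-to-end run configuration
#'
#' Bundles every component configuration of the pipeline
#' (simulate -> balance -> train -> extract -> expressivity -> evaluate ->
#' report) with a single global seed from which every stage derives its own
#' stream. The defaults describe the desk-scale study: a 2000-sample cohort
#' rendered at 64 pixels, a small conv backbone trained for 10 epochs, and a
#' 3-stage x 5-attribute expressivity grid averaged over 3 MINE seeds.
#'
#' @param seed global integer seed; all stage seeds are derived from it.
#' @param outdir output directory for all artifacts.
#' @param n cohort size.
#' @param image_size rendered image side in pixels.
#' @param split named fractions for train/val/test assignment.
#' @param cohort a [cohort_config()].
#' @param render a [render_config()].
#' @param backbone a [backbone_config()].
#' @param train a [train_run_config()].
#' @param mine_net a [statistics_net_config()].
#' @param mine_train a [mine_train_config()].
#' @param attributes cohort columns probed in the expressivity grid.
#' @param stages layer stages tapped for the grid.
#' @param expected_order expected expressivity ordering (most to least) used
#'   by the report's ordering verdict.
#' @param n_boot bootstrap resamples for the metric report.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       outdir = file.path(tempdir(), "expressivity_run"),
                       n = 2000L, image_size = 64L,
                       split = c(train = 0.7, val = 0.15, test = 0.15),
                       cohort = cohort_config(n = n,
                                              seed = derive_seed(seed, "cohort")),
                       render = render_config(size = image_size),
                       backbone = backbone_config("conv",
                                                  input_size = image_size,
                                                  base_width = 16L),
                       train = train_run_config(learning_rate = 1e-3,
                                                epochs = 10L,
                                                seed = derive_seed(seed, "train")),
                       mine_net = statistics_net_config(),
                       mine_train = mine_train_config(n_seeds = 3L),
                       attributes = c("age", "sex", "IVSDd", "LVPWDd", "LVIDd"),
                       stages = c("early", "mid", "final"),
                       expected_order = c("age", "sex", "IVSDd", "LVPWDd", "LVIDd"),
                       n_boot = 1000L) {
  stopifnot(abs(sum(split) - 1) < 1e-8, all(split > 0))
  cfg <- structure(list(seed = as.integer(seed), outdir = outdir,
                        n = as.integer(n), image_size = as.integer(image_size),
                        split = split, cohort = cohort, render = render,
                        backbone = backbone, train = train,
                        mine_net = mine_net, mine_train = mine_train,
                        attributes = attributes, stages = stages,
                        expected_order = expected_order,
                        n_boot = as.integer(n_boot)),
                   class = "run_config")
  cfg$config_hash <- hash_obj(cfg[setdiff(names(cfg), c("outdir", "config_hash"))])
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; nested sections
#' (`cohort`, `render`, `backbone`, `train`, `mine_net`, `mine_train`) hold
#' arguments of the corresponding constructors and may be partial.
#'
#' @param path YAML file.
#' @param seed,outdir optional overrides of the file's values.
#' @return a [run_config()].
#' @export
load_run_config <- function(path, seed = NULL, outdir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(outdir)) y$outdir <- outdir
  args <- list()
  for (key in c("seed", "outdir", "n", "image_size", "attributes", "stages",
                "expected_order", "n_boot")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$split)) args$split <- unlist(y$split)
  top_seed <- args$seed %||% 1L
  top_n <- args$n %||% 2000L
  top_size <- args$image_size %||% 64L
  sec <- function(name, ctor, extra = list()) {
    if (is.null(y[[name]]) && length(extra) == 0) return(NULL)
    do.call(ctor, utils::modifyList(extra, as.list(y[[name]] %||% list())))
  }
  args$cohort <- sec("cohort", cohort_config,
                     list(n = top_n, seed = derive_seed(top_seed, "cohort")))
  args$render <- sec("render", render_config, list(size = top_size))
  bb <- sec("backbone", backbone_config,
            list(family = "conv", input_size = top_size, base_width = 16L))
  if (!is.null(bb)) args$backbone <- bb
  tr <- sec("train", train_run_config,
            list(learning_rate = 1e-3, epochs = 10L,
                 seed = derive_seed(top_seed, "train")))
  if (!is.null(tr)) args$train <- tr
  if (!is.null(y$mine_net)) args$mine_net <- do.call(statistics_net_config,
                                                     y$mine_net)
  if (!is.null(y$mine_train)) args$mine_train <- do.call(mine_train_config,
                                                         y$mine_train)
  do.call(run_config, args[!vapply(args, is.null, TRUE)])
}

manifest_path <- function(outdir) file.path(outdir, "manifest.json")

read_manifest <- function(outdir) {
  p <- manifest_path(outdir)
  if (!file.exists(p)) {
    return(list(config_hash = NULL,
                package_version = as.character(utils::packageVersion("expressivity")),
                stages = list()))
  }
  jsonlite::read_json(p)
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, manifest_path(outdir), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}

# a stage is current if it completed under the same config hash and all of
# its recorded outputs still exist with matching checksums
stage_current <- function(manifest, cfg, stage) {
  st <- manifest$stages[[stage]]
  if (is.null(st)) return(FALSE)
  if (!identical(st$config_hash, cfg$config_hash)) return(FALSE)
  for (f in st$outputs) {
    path <- file.path(cfg$outdir, f$file)
    if (!file.exists(path)) return(FALSE)
    if (!identical(unname(tools::md5sum(path)), f$md5)) return(FALSE)
  }
  TRUE
}

record_stage <- function(manifest, cfg, stage, files, wall_time,
                         warnings = character(0), cached = FALSE) {
  manifest$config_hash <- cfg$config_hash
  manifest$package_version <-
    as.character(utils::packageVersion("expressivity"))
  manifest$stages[[stage]] <- list(
    config_hash = cfg$config_hash,
    outputs = lapply(files, function(f)
      list(file = f, md5 = unname(tools::md5sum(file.path(cfg$outdir, f))))),
    wall_time_s = round(wall_time, 3),
    warnings = as.list(warnings),
    cached = cached)
  manifest
}

load_cohort <- function(cfg) {
  df <- utils::read.csv(file.path(cfg$outdir, "cohort.csv"),
                        stringsAsFactors = FALSE)
  df
}

#' Read a rendered image set from a directory of PNG files
#'
#' @param dir directory holding `<sample_id>.png` files.
#' @param sample_ids ids to load, in order.
#' @return an `image_set` matrix (rows in `sample_ids` order).
#' @export
load_images <- function(dir, sample_ids) {
  n <- length(sample_ids)
  first <- png::readPNG(file.path(dir, paste0(sample_ids[1], ".png")))
  S <- nrow(first)
  out <- matrix(0, n, S * S)
  out[1, ] <- as.numeric(first)
  if (n > 1) {
    for (i in 2:n) {
      out[i, ] <- as.numeric(png::readPNG(file.path(
        dir, paste0(sample_ids[i], ".png"))))
    }
  }
  structure(out, size = S, sample_ids = sample_ids, class = "image_set")
}

write_images <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  S <- attr(images, "size")
  ids <- attr(images, "sample_ids")
  for (i in seq_len(nrow(images))) {
    png::writePNG(matrix(images[i, ], S, S),
                  file.path(dir, paste0(ids[i], ".png")))
  }
  invisible(dir)
}

load_balance <- function(cfg) {
  b <- jsonlite::read_json(file.path(cfg$outdir, "balance.json"),
                           simplifyVector = TRUE)
  b$indices <- lapply(b$indices, as.integer)
  b
}

#' Run one pipeline stage
#'
#' Stages are idempotent given the config hash: when a stage's outputs exist,
#' are current and checksum-clean, it is skipped (recorded as a cache hit)
#' unless `force = TRUE`. A stage whose upstream outputs are missing errors
#' and names the stage to run first.
#'
#' @param cfg a [run_config()].
#' @param stage one of `simulate`, `balance`, `train`, `extract`,
#'   `expressivity`, `evaluate`, `report`.
#' @param force recompute even if outputs are current.
#' @return the updated manifest, invisibly.
#' @export
run_stage <- function(cfg, stage = PIPELINE_STAGES, force = FALSE) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_manifest(cfg$outdir)

  need <- function(upstream, file) {
    if (!file.exists(file.path(cfg$outdir, file))) {
      stop(sprintf("missing artifact '%s'; run stage '%s' first", file,
                   upstream), call. = FALSE)
    }
  }

  if (!force && stage_current(manifest, cfg, stage)) {
    st <- manifest$stages[[stage]]
    st$cached <- TRUE
    manifest$stages[[stage]] <- st
    message(sprintf("[%s] up-to-date, skipping (cache hit)", stage))
    write_manifest(manifest, cfg$outdir)
    return(invisible(manifest))
  }

  t0 <- Sys.time()
  warns <- character(0)
  files <- switch(
    stage,
    simulate = {
      cohort <- sample_cohort(cfg$cohort)
      write_cohort(cohort, file.path(cfg$outdir, "cohort.csv"))
      imgs <- render_images(cohort, cfg$render,
                            seed = derive_seed(cfg$seed, "render"))
      write_images(imgs, file.path(cfg$outdir, "images"))
      jsonlite::write_json(
        list(config_hash = hash_obj(cfg$render),
             seed = derive_seed(cfg$seed, "render"), n = nrow(imgs)),
        file.path(cfg$outdir, "images_provenance.json"), auto_unbox = TRUE)
      c("cohort.csv", "cohort_provenance.json", "images_provenance.json")
    },
    balance = {
      need("simulate", "cohort.csv")
      cohort <- load_cohort(cfg)
      assign_split <- with_local_seed(derive_seed(cfg$seed, "split"), {
        sample(rep(names(cfg$split),
                   diff(round(cumsum(c(0, cfg$split)) * nrow(cohort)))))
      })
      bal <- make_balanced_subset(cohort$slvh, assign_split,
                                  seed = derive_seed(cfg$seed, "balance"))
      jsonlite::write_json(list(split = assign_split, indices = bal,
                                counts = as.data.frame(attr(bal, "counts"))),
                           file.path(cfg$outdir, "balance.json"),
                           auto_unbox = FALSE, digits = NA)
      "balance.json"
    },
    train = {
      need("balance", "balance.json")
      cohort <- load_cohort(cfg)
      bal <- load_balance(cfg)
      imgs <- load_images(file.path(cfg$outdir, "images"), cohort$sample_id)
      model <- build_backbone(cfg$backbone,
                              seed = derive_seed(cfg$seed, "init"))
      model <- train_classifier(model,
                                imgs[bal$indices$train, ],
                                cohort$slvh[bal$indices$train],
                                imgs[bal$indices$val, ],
                                cohort$slvh[bal$indices$val], cfg$train)
      saveRDS(model, file.path(cfg$outdir, "checkpoint.rds"))
      jsonlite::write_json(model$history,
                           file.path(cfg$outdir, "train_history.json"),
                           auto_unbox = TRUE, digits = NA)
      c("checkpoint.rds", "train_history.json")
    },
    extract = {
      need("train", "checkpoint.rds")
      cohort <- load_cohort(cfg)
      bal <- load_balance(cfg)
      model <- readRDS(file.path(cfg$outdir, "checkpoint.rds"))
      imgs <- load_images(file.path(cfg$outdir, "images"), cohort$sample_id)
      idx <- bal$indices$train
      out <- character(0)
      for (tag in cfg$stages) {
        fm <- extract_features(model, imgs[idx, ], tag)
        df <- data.frame(sample_id = cohort$sample_id[idx], fm$values,
                         check.names = FALSE)
        names(df) <- c("sample_id", paste0("f_", seq_len(ncol(fm$values)) - 1))
        f <- sprintf("features_%s.csv", tag)
        utils::write.csv(df, file.path(cfg$outdir, f), row.names = FALSE)
        out <- c(out, f)
      }
      out
    },
    expressivity = {
      need("extract", sprintf("features_%s.csv", cfg$stages[1]))
      need("simulate", "cohort.csv")
      cohort <- load_cohort(cfg)
      bal <- load_balance(cfg)
      model <- readRDS(file.path(cfg$outdir, "checkpoint.rds"))
      imgs <- load_images(file.path(cfg$outdir, "images"), cohort$sample_id)
      idx <- bal$indices$train
      prof <- expressivity_profile(model, imgs[idx, ], cohort[idx, ],
                                   cfg$attributes, cfg$stages,
                                   cfg$mine_net, cfg$mine_train,
                                   seed0 = derive_seed(cfg$seed, "mine"))
      if (any(prof$grid$negative_flag)) {
        warns <- c(warns, "negative per-seed MI estimate in the grid")
      }
      write_expressivity_json(prof$cells,
                              file.path(cfg$outdir, "expressivity.json"))
      utils::write.csv(prof$grid,
                       file.path(cfg$outdir, "expressivity_grid.csv"),
                       row.names = FALSE)
      c("expressivity.json", "expressivity_grid.csv")
    },
    evaluate = {
      need("train", "checkpoint.rds")
      cohort <- load_cohort(cfg)
      bal <- load_balance(cfg)
      model <- readRDS(file.path(cfg$outdir, "checkpoint.rds"))
      imgs <- load_images(file.path(cfg$outdir, "images"), cohort$sample_id)
      idx <- bal$indices$test
      p <- predict_proba(model, imgs[idx, ])
      rep <- metric_report(p, cohort$slvh[idx], n_boot = cfg$n_boot,
                           seed = derive_seed(cfg$seed, "bootstrap"))
      jsonlite::write_json(
        list(auroc = rep$auroc, auroc_ci = rep$auroc_ci,
             auprc = rep$auprc, auprc_ci = rep$auprc_ci,
             level = rep$level, n_boot = rep$n_boot, n = rep$n),
        file.path(cfg$outdir, "metrics.json"), auto_unbox = TRUE, digits = NA)
      utils::write.csv(rep$roc, file.path(cfg$outdir, "roc_curve.csv"),
                       row.names = FALSE)
      utils::write.csv(rep$pr, file.path(cfg$outdir, "pr_curve.csv"),
                       row.names = FALSE)
      c("metrics.json", "roc_curve.csv", "pr_curve.csv")
    },
    report = {
      need("evaluate", "metrics.json")
      rep <- build_report(cfg)
      jsonlite::write_json(rep$json, file.path(cfg$outdir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      writeLines(rep$text, file.path(cfg$outdir, "report.txt"))
      c("report.json", "report.txt")
    })

  wall <- as.numeric(Sys.time() - t0, units = "secs")
  manifest <- record_stage(manifest, cfg, stage, files, wall, warns)
  message(sprintf("[%s] done in %.1fs", stage, wall))
  write_manifest(manifest, cfg$outdir)
  invisible(manifest)
}

build_report <- function(cfg) {
  metrics <- jsonlite::read_json(file.path(cfg$outdir, "metrics.json"),
                                 simplifyVector = TRUE)
  grid_file <- file.path(cfg$outdir, "expressivity_grid.csv")
  lines <- c("== Classification metrics (test split) ==",
             sprintf("AUROC %.3f [%.0f%% CI: %.3f-%.3f]", metrics$auroc,
                     100 * metrics$level, metrics$auroc_ci[1],
                     metrics$auroc_ci[2]),
             sprintf("AUPRC %.3f [%.0f%% CI: %.3f-%.3f]", metrics$auprc,
                     100 * metrics$level, metrics$auprc_ci[1],
                     metrics$auprc_ci[2]))
  json <- list(metrics = metrics, config_hash = cfg$config_hash)
  if (file.exists(grid_file)) {
    grid <- utils::read.csv(grid_file, stringsAsFactors = FALSE)
    lines <- c(lines, "", "== Expressivity grid (nats, mean +/- std) ==")
    for (st in unique(grid$stage)) {
      g <- grid[grid$stage == st, ]
      cells <- sprintf("%s %.3f+/-%.3f%s", g$attribute, g$mean, g$std,
                       ifelse(g$negative_flag, " [neg-flag]", ""))
      lines <- c(lines, sprintf("%-6s %s", st, paste(cells, collapse = "  ")))
    }
    final_stage <- cfg$stages[length(cfg$stages)]
    means <- with(grid[grid$stage == final_stage, ],
                  stats::setNames(mean, attribute))
    oc <- ordering_check(means, expected = cfg$expected_order)
    verdict <- if (oc$tie) "TIE" else if (oc$match) "MATCH" else "MISMATCH"
    lines <- c(lines, "",
               sprintf("ordering: %s (tau=%.2f) [expected %s]", verdict,
                       oc$tau, paste(cfg$expected_order, collapse = " > ")))
    if (any(grid$negative_flag)) {
      lines <- c(lines,
                 "note: raw negative MI estimates present (reported unclipped)")
    }
    json$expressivity <- grid
    json$ordering <- list(match = oc$match, tau = oc$tau, tie = oc$tie,
                          estimated_order = oc$estimated_order,
                          expected_order = oc$expected_order)
  } else {
    lines <- c(lines, "", "expressivity grid omitted: stage not run")
    json$expressivity <- NULL
  }
  list(json = json, text = lines)
}

#' Run the full pipeline
#'
#' Executes every stage in order under one configuration. Stages whose
#' outputs are already current are skipped unless `force = TRUE`.
#'
#' @param cfg a [run_config()].
#' @param force recompute all stages.
#' @return the final manifest, invisibly.
#' @export
run_pipeline <- function(cfg, force = FALSE) {
  for (st in PIPELINE_STAGES) run_stage(cfg, st, force = force)
  invisible(read_manifest(cfg$outdir))
}

#' Human-readable run summary
#'
#' Renders the metric table with confidence intervals, the layer-by-attribute
#' expressivity table (mean +/- std per cell), and the ordering-check
#' verdict; raw negative estimates are shown with a flag, and a missing
#' expressivity grid is noted explicitly.
#'
#' @param cfg a [run_config()] whose `report` stage has run (or at least
#'   `evaluate`).
#' @return the report lines, invisibly; they are also printed.
#' @export
report_summary <- function(cfg) {
  rep <- build_report(cfg)
  cat(paste(rep$text, collapse = "\n"), "\n")
  invisible(rep$text)
}
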