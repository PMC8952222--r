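# Orchestration: a single validated configuration, staged execution with
# completion markers and resumability, parallel per-pair scanning with
# worker-count-independent results, and a machine-readable run manifest.

pipeline_defaults <- function() {
  list(
    # curation
    min_identity = 35, max_gaps = 25, divergence_cutoff = 0.95,
    identity_denom = "aligned",
    # pairing
    min_shared = 20,
    # engine
    alpha = 0.01, bootstrap_threshold = 0.6, bootstrap_reps = 100,
    null_samples = 10000, min_pair_fraction = 0.5, tail = "positive",
    matrix = "BLOSUM62", t_min = 1e-6, min_subst = 2,
    variation = "binary", null_method = "paired", ref_species = NULL,
    # quality
    min_block = 10, max_nonconserved_stretch = 8,
    # filters
    p_max = 0.005, gap_max = 0.20, require_good = TRUE,
    fdr_scope = "pooled",
    # execution
    workers = 1, seed = 1, work_dir = "coev_work", input_dir = NULL)
}

parse_settings_conf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop_coev("coev_config", "cannot parse config line: '%s'", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (val %in% c("true", "TRUE", "yes")) TRUE
      else if (val %in% c("false", "FALSE", "no")) FALSE
      else val
  }
  out
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (`.yaml`/`.yml`) or a `key = value` settings file,
#' applies the defaults, and validates every field; unknown keys and every
#' range violation are reported together.
#'
#' @param path Optional config file; `NULL` gives pure defaults.
#' @param overrides Named list overriding file values (e.g. from CLI flags).
#' @return A validated list of class `coev_config`.
#' @export
validate_config <- function(path = NULL, overrides = list()) {
  defaults <- pipeline_defaults()
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_coev("coev_config", "config file not found: %s", path)
    vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) %||% list()
      else parse_settings_conf(path)
  }
  vals[names(overrides)] <- overrides
  errors <- character(0)
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown))
    errors <- c(errors, sprintf("unknown key: %s", unknown))
  cfg <- defaults
  cfg[intersect(names(vals), names(defaults))] <-
    vals[intersect(names(vals), names(defaults))]
  rng <- function(key, lo, hi) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi)
      errors <<- c(errors, sprintf("%s must be in [%g, %g]", key, lo, hi))
  }
  rng("min_identity", 0, 100); rng("max_gaps", 0, 100)
  rng("divergence_cutoff", 0, 1); rng("min_shared", 2, Inf)
  rng("alpha", 1e-12, 1 - 1e-12); rng("bootstrap_threshold", 0, 1)
  rng("bootstrap_reps", 1, Inf); rng("null_samples", 100, Inf)
  rng("min_pair_fraction", 0, 1); rng("t_min", 1e-300, Inf)
  rng("min_subst", 0, Inf); rng("p_max", 0, 1); rng("gap_max", 0, 1)
  rng("workers", 1, Inf); rng("min_block", 1, Inf)
  rng("max_nonconserved_stretch", 0, Inf)
  for (key in c("tail", "variation", "null_method", "fdr_scope")) {
    choices <- list(tail = c("positive", "two_sided"),
                    variation = c("binary", "blosum", "classic"),
                    null_method = c("paired", "permuted"),
                    fdr_scope = c("pooled", "per_pair"))[[key]]
    if (!cfg[[key]] %in% choices)
      errors <- c(errors, sprintf("%s must be one of: %s", key,
                                  paste(choices, collapse = ", ")))
  }
  if (length(errors))
    stop_coev("coev_config", "invalid configuration:\n  %s",
              paste(errors, collapse = "\n  "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "coev_config")
}

config_engine <- function(cfg) {
  engine_config(alpha = cfg$alpha, bootstrap_threshold = cfg$bootstrap_threshold,
                bootstrap_reps = cfg$bootstrap_reps,
                null_samples = cfg$null_samples, seed = cfg$seed,
                min_pair_fraction = cfg$min_pair_fraction, tail = cfg$tail,
                matrix = cfg$matrix, t_min = cfg$t_min,
                min_subst = cfg$min_subst, variation = cfg$variation,
                null_method = cfg$null_method, ref_species = cfg$ref_species)
}

PIPELINE_STAGES <- c("curate", "quality", "pair", "scan", "post", "export")

marker_path <- function(cfg, stage) file.path(cfg$work_dir, "status",
                                              paste0(stage, ".done"))

read_input_msas <- function(cfg) {
  input <- cfg$input_dir %||% file.path(cfg$work_dir, "input")
  msa_dir <- if (dir.exists(file.path(cfg$work_dir, "curated")))
    file.path(cfg$work_dir, "curated") else file.path(input, "msa")
  files <- sort(list.files(msa_dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  if (!length(files))
    stop_coev("coev_stage", "no alignments found in %s", msa_dir)
  msas <- lapply(files, read_msa)
  names(msas) <- vapply(msas, `[[`, "", "protein_id")
  msas[sort(names(msas))]
}

read_input_tree <- function(cfg) {
  input <- cfg$input_dir %||% file.path(cfg$work_dir, "input")
  tp <- file.path(input, "tree.nwk")
  if (file.exists(tp)) read_newick(tp) else NULL
}

stage_curate <- function(cfg) {
  input <- cfg$input_dir %||% file.path(cfg$work_dir, "input")
  cand_dir <- file.path(input, "candidates")
  if (!dir.exists(cand_dir))
    return(list(skipped = TRUE, note = "no candidate sets; inputs treated as curated"))
  out_dir <- file.path(cfg$work_dir, "curated")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rej_all <- list()
  for (f in sort(list.files(cand_dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))) {
    pid <- sub("\\.[^.]*$", "", basename(f))
    recs <- Biostrings::readBStringSet(f)
    parts <- strsplit(sub("\\s.*$", "", names(recs)), "|", fixed = TRUE)
    cand <- data.frame(
      species = vapply(parts, `[`, "", 1),
      candidate_id = vapply(parts, function(p) p[min(2, length(p))], ""),
      sequence = as.character(recs), stringsAsFactors = FALSE)
    ref_file <- file.path(input, "reference", paste0(pid, ".fasta"))
    if (!file.exists(ref_file))
      stop_coev("coev_stage", "missing reference sequence for %s", pid)
    reference <- gsub("-", "", as.character(Biostrings::readBStringSet(ref_file))[1])
    sel <- select_best_hit(
      list(protein_id = pid, reference = reference,
           candidates = within(cand, sequence <- gsub("-", "", sequence))),
      min_identity = cfg$min_identity, max_gaps = cfg$max_gaps,
      matrix = cfg$matrix, identity_denom = cfg$identity_denom)
    keep_seq <- cand$sequence[match(paste(sel$selected$species, sel$selected$candidate_id),
                                    paste(cand$species, cand$candidate_id))]
    names(keep_seq) <- sel$selected$species
    if (length(keep_seq) >= 4) {
      scr <- divergence_screen(keep_seq, cutoff = cfg$divergence_cutoff)
      keep_seq <- scr$retained
    }
    # curated sequences may be unaligned; write plain FASTA
    set <- Biostrings::BStringSet(unname(keep_seq))
    names(set) <- names(keep_seq)
    Biostrings::writeXStringSet(set, file.path(out_dir, paste0(pid, ".fasta")),
                                width = 60L)
    rej_all[[pid]] <- sel$rejected
  }
  rej <- do.call(rbind, c(rej_all, make.row.names = FALSE))
  utils::write.table(rej, file.path(cfg$work_dir, "curation_rejections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(skipped = FALSE, n_proteins = length(list.files(out_dir)))
}

stage_quality <- function(cfg, msas) {
  qdir <- file.path(cfg$work_dir, "quality")
  dir.create(qdir, recursive = TRUE, showWarnings = FALSE)
  qual <- lapply(msas, column_quality, min_block = cfg$min_block,
                 max_nonconserved_stretch = cfg$max_nonconserved_stretch)
  for (id in names(qual))
    write_quality_tsv(qual[[id]], file.path(qdir, paste0(id, ".tsv")))
  qual
}

read_quality <- function(cfg, ids) {
  qdir <- file.path(cfg$work_dir, "quality")
  qual <- lapply(ids, function(id) {
    q <- utils::read.delim(file.path(qdir, paste0(id, ".tsv")))
    data.frame(column = q$column_1based, gap_fraction = q$gap_fraction,
               class = q$class, good = q$good == 1L, stringsAsFactors = FALSE)
  })
  names(qual) <- ids
  qual
}

stage_pair <- function(cfg, msas, tree) {
  pairs <- enumerate_pairs(names(msas))
  pdir <- file.path(cfg$work_dir, "pairs")
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  rejections <- list()
  accepted <- character(0)
  for (k in seq_len(nrow(pairs))) {
    pin <- build_pair_input(msas[[pairs$a[k]]], msas[[pairs$b[k]]],
                            tree_a = tree, tree_b = tree,
                            min_shared = cfg$min_shared)
    if (inherits(pin, "coev_pair_rejection")) {
      rejections[[pin$pair_id]] <- data.frame(
        pair = pin$pair_id, n_shared = pin$n_shared, reason = pin$reason,
        stringsAsFactors = FALSE)
      next
    }
    d <- file.path(pdir, pin$pair_id)
    dir.create(d, showWarnings = FALSE)
    write_msa(pin$msa_a, file.path(d, paste0(pin$msa_a$protein_id, ".fasta")))
    write_msa(pin$msa_b, file.path(d, paste0(pin$msa_b$protein_id, ".fasta")))
    if (!is.null(pin$tree_a))
      write_newick(pin$tree_a, file.path(d, paste0(pin$msa_a$protein_id, ".nwk")))
    if (!is.null(pin$tree_b))
      write_newick(pin$tree_b, file.path(d, paste0(pin$msa_b$protein_id, ".nwk")))
    accepted <- c(accepted, pin$pair_id)
  }
  rej <- if (length(rejections)) do.call(rbind, c(unname(rejections), make.row.names = FALSE))
    else data.frame(pair = character(), n_shared = integer(), reason = character())
  utils::write.table(rej, file.path(pdir, "rejections.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(accepted = sort(accepted), rejected = rej)
}

stage_scan <- function(cfg, msas, tree, qual) {
  ecfg <- config_engine(cfg)
  pairs <- enumerate_pairs(names(msas))
  pdir <- file.path(cfg$work_dir, "pairs")
  todo <- pairs[dir.exists(file.path(pdir, pairs$pair_id)), , drop = FALSE]
  scan_one <- function(k) {
    a <- todo$a[k]; b <- todo$b[k]
    pin <- build_pair_input(msas[[a]], msas[[b]], tree_a = tree, tree_b = tree,
                            min_shared = cfg$min_shared)
    res <- tryCatch(
      bidirectional_scan(pin, ecfg, quality_a = qual[[a]], quality_b = qual[[b]]),
      error = function(e) e)
    res
  }
  results <- if (cfg$workers > 1) {
    parallel::mclapply(seq_len(nrow(todo)), scan_one,
                       mc.cores = cfg$workers, mc.preschedule = TRUE)
  } else lapply(seq_len(nrow(todo)), scan_one)
  names(results) <- todo$pair_id
  failures <- character(0)
  for (id in todo$pair_id) {
    d <- file.path(pdir, id)
    r <- results[[id]]
    if (inherits(r, "error")) {
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(r)))
      writeLines(sprintf("error\t%s", conditionMessage(r)),
                 file.path(d, "log.tsv"))
      next
    }
    utils::write.table(format_table(r$hits), file.path(d, "hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lg <- r$log_fwd
    log_df <- data.frame(
      key = c("pair_id", "n_usable_a", "n_usable_b", "n_comparisons",
              "n_hits", "aborted", "reason", "rev_run"),
      value = c(lg$pair_id, lg$n_usable_a, lg$n_usable_b, lg$n_comparisons,
                nrow(r$hits), lg$aborted,
                if (is.na(lg$reason)) "" else lg$reason,
                !is.null(r$log_rev)))
    utils::write.table(log_df, file.path(d, "log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  list(results = results[!vapply(results, inherits, TRUE, "error")],
       failures = failures)
}

read_scans <- function(cfg) {
  pdir <- file.path(cfg$work_dir, "pairs")
  ids <- sort(setdiff(list.dirs(pdir, recursive = FALSE, full.names = FALSE), ""))
  scans <- list()
  for (id in ids) {
    lf <- file.path(pdir, id, "log.tsv")
    hf <- file.path(pdir, id, "hits.tsv")
    if (!file.exists(lf) || !file.exists(hf)) next
    kv <- utils::read.delim(lf, header = FALSE, col.names = c("key", "value"),
                            colClasses = "character")
    if (kv$key[1] == "error") next
    get <- function(k) kv$value[match(k, kv$key)]
    hits <- utils::read.delim(hf, colClasses = NA, stringsAsFactors = FALSE)
    if (nrow(hits)) {
      hits$residue_a <- as.character(hits$residue_a)
      hits$residue_b <- as.character(hits$residue_b)
      hits$good_a <- as.logical(hits$good_a)
      hits$good_b <- as.logical(hits$good_b)
    }
    scans[[id]] <- list(
      hits = hits,
      log_fwd = list(pair_id = id,
                     n_usable_a = as.integer(get("n_usable_a")),
                     n_usable_b = as.integer(get("n_usable_b")),
                     n_comparisons = as.integer(get("n_comparisons")),
                     aborted = as.logical(get("aborted")),
                     reason = get("reason")),
      log_rev = if (identical(get("rev_run"), "TRUE")) list() else NULL)
  }
  scans
}

stage_post <- function(cfg) {
  scans <- read_scans(cfg)
  if (!length(scans)) stop_coev("coev_stage", "no scanned pairs found; run 'scan' first")
  res <- collect_results(scans, fdr_scope = cfg$fdr_scope)
  if (sum(res$pair_table$n_comparisons > 0) >= 2L)
    res <- suppressWarnings(chisq_pairs(res))
  write_result_tables(res, file.path(cfg$work_dir, "results"))
  filtered <- filter_results(res, p_max = cfg$p_max,
                             require_good = cfg$require_good,
                             gap_max = cfg$gap_max)
  write_result_tables(filtered, file.path(cfg$work_dir, "results", "filtered"))
  list(results = res, filtered = filtered)
}

stage_export <- function(cfg, post) {
  export_network(post$results, file.path(cfg$work_dir, "network"))
  export_network(post$filtered, file.path(cfg$work_dir, "network", "filtered"))
  invisible(NULL)
}

#' Run the screening pipeline
#'
#' Executes the requested stages in order (curate, quality, pair, scan,
#' post, export). Each completed stage writes a marker under
#' `<work_dir>/status/`; re-running skips completed stages unless
#' `force = TRUE`. Per-pair scanning is distributed over `workers`
#' processes; per-pair seeds derive from the global seed and the pair id,
#' so results are independent of worker count and input order.
#'
#' Expected input layout (under `input_dir`): `msa/<protein>.fasta`
#' (aligned, one sequence per species) and optionally `tree.nwk` (species
#' tree) and `candidates/` + `reference/` for the curation stage.
#'
#' @param config A `coev_config` from [validate_config()] (or a named list
#'   of overrides).
#' @param stages Stages to run (default: all, in order).
#' @param force Re-run stages whose markers exist.
#' @return List of class `coev_run` with `status` (0 ok, 2 if any pair
#'   failed), `stages_run`, `n_pairs`, `n_aborted`, `failures`, and for a
#'   run including `post` the `results`/`filtered` tables.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES, force = FALSE) {
  cfg <- if (inherits(config, "coev_config")) config
    else validate_config(NULL, overrides = config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(file.path(cfg$work_dir, "status"), recursive = TRUE,
             showWarnings = FALSE)
  ran <- character(0)
  failures <- character(0)
  post <- NULL
  msas <- NULL; tree <- NULL; qual <- NULL
  need_inputs <- function() {
    if (is.null(msas)) {
      msas <<- read_input_msas(cfg)
      tree <<- read_input_tree(cfg)
    }
  }
  for (st in stages) {
    mk <- marker_path(cfg, st)
    if (file.exists(mk) && !force) next
    switch(st,
      curate = { stage_curate(cfg) },
      quality = { need_inputs(); qual <- stage_quality(cfg, msas) },
      pair = { need_inputs(); stage_pair(cfg, msas, tree) },
      scan = {
        need_inputs()
        if (is.null(qual)) qual <- tryCatch(read_quality(cfg, names(msas)),
                                            error = function(e) NULL)
        if (is.null(qual)) qual <- stage_quality(cfg, msas)
        sc <- stage_scan(cfg, msas, tree, qual)
        failures <- c(failures, sc$failures)
      },
      post = { post <- stage_post(cfg) },
      export = {
        if (is.null(post)) post <- stage_post(cfg)
        stage_export(cfg, post)
      })
    writeLines(st, mk)
    ran <- c(ran, st)
  }
  scans <- read_scans(cfg)
  n_aborted <- sum(vapply(scans, function(s) isTRUE(s$log_fwd$aborted), TRUE))
  manifest <- list(package = "coevscreen",
                   version = as.character(utils::packageVersion("coevscreen")),
                   seed = cfg$seed,
                   config = unclass(cfg)[order(names(unclass(cfg)))],
                   stages_run = ran)
  jsonlite::write_json(manifest, file.path(cfg$work_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  structure(list(status = if (length(failures) || n_aborted > 0L) 2L else 0L,
                 stages_run = ran, n_pairs = length(scans),
                 n_aborted = n_aborted, failures = failures,
                 results = post$results, filtered = post$filtered),
            class = "coev_run")
}

#' @export
print.coev_run <- function(x, ...) {
  cat(sprintf("<coev_run> stages [%s], %d pairs scanned (%d aborted), status %d\n",
              paste(x$stages_run, collapse = ", "), x$n_pairs, x$n_aborted,
              x$status))
  invisible(x)
}
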