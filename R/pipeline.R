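# Orchestration: a file-backed workspace with a persistent FIFO job queue
# and permanent per-stage parameter provenance. Mirrors the wizard flow:
# collection import -> BLAST parse -> network/screening (optional halt) ->
# sequence selection -> alignment -> distances -> tree, with many-to-one
# fan-out from one screening report to several alignments and from one
# alignment to several trees.

.STAGES <- c("import", "blast", "screen", "align", "tree", "full")

.WS_DIRS <- c("collections", "blast", "networks", "reports", "alignments",
              "trees", "provenance", "queue")

#' Open (or create) a pipeline workspace
#'
#' A workspace is a directory with one subdirectory per artifact kind
#' (`collections/`, `blast/`, `networks/`, `reports/`, `alignments/`,
#' `trees/`, `provenance/`) plus the queue state under `queue/`.
#'
#' @param dir workspace directory; created if absent.
#' @return an object of class `workspace`.
#' @export
workspace <- function(dir) {
  stopifnot(.is_string(dir))
  for (d in file.path(dir, .WS_DIRS)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  structure(list(dir = normalizePath(dir)), class = "workspace")
}

#' @export
print.workspace <- function(x, ...) {
  jobs <- .queue_read(x)
  cat(sprintf("<workspace> %s: %d job(s) (%d queued)\n", x$dir, length(jobs),
              sum(vapply(jobs, function(j) j$state, character(1)) == "queued")))
  invisible(x)
}

.queue_file <- function(ws) file.path(ws$dir, "queue", "jobs.json")

.queue_read <- function(ws) {
  f <- .queue_file(ws)
  if (!file.exists(f)) return(list())
  jsonlite::fromJSON(f, simplifyVector = FALSE)
}

# Atomic persist: write to a temp file in the same directory, then rename.
.queue_write <- function(ws, jobs) {
  f <- .queue_file(ws)
  tmp <- paste0(f, ".tmp")
  writeLines(jsonlite::toJSON(jobs, auto_unbox = TRUE, null = "null",
                              digits = NA, pretty = TRUE), tmp)
  file.rename(tmp, f)
  invisible(jobs)
}

#' Enqueue a pipeline job
#'
#' Jobs are persisted immediately in state `queued` and serviced in FIFO
#' order of submission. A `full` job runs the whole staged pipeline from
#' its config.
#'
#' @param ws a [workspace()].
#' @param stage one of `import`, `blast`, `screen`, `align`, `tree`, `full`.
#' @param params named list of stage parameters (must be serializable).
#' @return the persisted job, invisibly (a named list; see `job_status()`).
#' @export
enqueue <- function(ws, stage, params = list()) {
  stopifnot(inherits(ws, "workspace"))
  if (!.is_string(stage) || !(stage %in% .STAGES)) {
    stop(sprintf("unknown stage '%s'; expected one of %s",
                 as.character(stage)[1], paste(.STAGES, collapse = ", ")),
         call. = FALSE)
  }
  jobs <- .queue_read(ws)
  job <- list(id = sprintf("job-%05d", length(jobs) + 1L), stage = stage,
              params = params, state = "queued",
              submitted_at = .timestamp(), started_at = NULL,
              finished_at = NULL, error_message = NULL,
              artifact_paths = list())
  jobs[[length(jobs) + 1L]] <- job
  .queue_write(ws, jobs)
  invisible(job)
}

#' Run the oldest queued job
#'
#' Transitions the job `queued -> running -> done|failed`, persisting each
#' transition. A stage failure marks only that job failed (with its error
#' message) and leaves the queue and other jobs' artifacts intact. An
#' empty queue is a no-op returning `NULL`.
#'
#' @param ws a [workspace()].
#' @return the finished job, or `NULL` when nothing was queued.
#' @export
run_next <- function(ws) {
  stopifnot(inherits(ws, "workspace"))
  jobs <- .queue_read(ws)
  idx <- which(vapply(jobs, function(j) j$state, character(1)) == "queued")
  if (!length(idx)) return(invisible(NULL))
  k <- idx[1L]
  jobs[[k]]$state <- "running"
  jobs[[k]]$started_at <- .timestamp()
  .queue_write(ws, jobs)
  res <- tryCatch({
    paths <- .run_stage(ws, jobs[[k]])
    list(ok = TRUE, paths = paths)
  }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
  jobs <- .queue_read(ws)  # re-read: the stage may have enqueued sub-jobs
  jobs[[k]]$finished_at <- .timestamp()
  if (res$ok) {
    jobs[[k]]$state <- "done"
    jobs[[k]]$artifact_paths <- as.list(res$paths)
  } else {
    jobs[[k]]$state <- "failed"
    jobs[[k]]$error_message <- res$msg
  }
  .queue_write(ws, jobs)
  invisible(jobs[[k]])
}

#' Look up a job by id
#'
#' @param ws a [workspace()].
#' @param id job id.
#' @return the persisted job as a named list (`id`, `stage`, `params`,
#'   `state`, timestamps, `error_message`, `artifact_paths`).
#' @export
job_status <- function(ws, id) {
  jobs <- .queue_read(ws)
  ids <- vapply(jobs, function(j) j$id, character(1))
  if (!(id %in% ids)) stop(sprintf("unknown job id '%s'", id), call. = FALSE)
  jobs[[match(id, ids)]]
}

#' List persisted jobs
#'
#' @param ws a [workspace()].
#' @param state optional filter: one of `queued`, `running`, `done`,
#'   `failed`.
#' @return a data frame with one row per job.
#' @export
list_jobs <- function(ws, state = NULL) {
  jobs <- .queue_read(ws)
  df <- data.frame(
    id = vapply(jobs, function(j) j$id, character(1)),
    stage = vapply(jobs, function(j) j$stage, character(1)),
    state = vapply(jobs, function(j) j$state, character(1)),
    submitted_at = vapply(jobs, function(j) j$submitted_at, character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(state)) df <- df[df$state == state, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---------------------------------------------------------------------------
# Stage execution

# Fill every defaulted parameter so provenance records the parameters
# actually used, not just those supplied.
.resolve_config <- function(config) {
  def <- list(
    name = "run",
    collection = list(file = NULL, text = NULL, format = "fasta",
                      name = NULL),
    blast = list(file = NULL, text = NULL, format = "tab"),
    network = list(max_evalue = NULL, min_bit_score = NULL,
                   min_percent_identity = NULL, max_rank = NULL,
                   count_self = FALSE),
    screening = list(min_associations = 2L, include_ids = character(),
                     exclude_ids = character()),
    halt_after_screening = FALSE,
    subject_db = NULL,
    alignments = list(default = list(match = 1, mismatch = -1, gap = -2)),
    trees = list(default = list(alignment = "default", model = "jc69",
                                clamp_negative = FALSE)))
  cfg <- utils::modifyList(def, config, keep.null = TRUE)
  # a supplied fan-out section replaces the default set entirely
  if (!is.null(config$alignments)) cfg$alignments <- config$alignments
  if (!is.null(config$trees)) cfg$trees <- config$trees
  if (is.null(cfg$collection$name)) cfg$collection$name <- cfg$name
  for (tn in names(cfg$trees)) {
    cfg$trees[[tn]] <- utils::modifyList(def$trees$default, cfg$trees[[tn]],
                                         keep.null = TRUE)
  }
  for (an in names(cfg$alignments)) {
    cfg$alignments[[an]] <- utils::modifyList(def$alignments$default,
                                              cfg$alignments[[an]],
                                              keep.null = TRUE)
  }
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON, one section per stage; see
#' [run_pipeline()] for the schema.
#'
#' @param path configuration file path.
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
}

# Single-stage execution driven by the job queue. Each stage reads its
# inputs from the workspace (or from params) and writes one artifact set.
.run_stage <- function(ws, job) {
  p <- job$params
  switch(job$stage,
    import = {
      reader <- switch(p$format %||% "fasta",
                       fasta = read_fasta, genbank = read_genbank,
                       raw = read_raw,
                       stop(sprintf("unknown import format '%s'", p$format),
                            call. = FALSE))
      recs <- if (!is.null(p$text)) reader(text = p$text) else reader(p$file)
      coll <- create_collection(p$name %||% "collection", recs,
                                import_params = list(source_file = p$file %||% "inline"))
      out <- file.path(ws$dir, "collections", paste0(coll$name, ".fasta"))
      write_fasta(coll$records, out)
      out
    },
    blast = {
      results <- .parse_blast_any(p)
      out <- file.path(ws$dir, "blast", paste0((p$name %||% "blast"), ".tsv"))
      .write_results_tsv(results, out)
      out
    },
    screen = {
      results <- parse_blast_tabular(file.path(ws$dir, "blast",
                                               paste0((p$name %||% "blast"), ".tsv")))
      gate <- edge_gate(max_evalue = p$max_evalue,
                        min_bit_score = p$min_bit_score,
                        min_percent_identity = p$min_percent_identity,
                        max_rank = p$max_rank)
      net <- build_network(results, gate = gate,
                           count_self = isTRUE(p$count_self))
      crit <- screening_criteria(p$min_associations %||% 2L, gate = gate,
                                 include_ids = unlist(p$include_ids) %||% character(),
                                 exclude_ids = unlist(p$exclude_ids) %||% character())
      rep <- apply_screening(net, crit)
      base <- p$name %||% "screen"
      paths <- c(file.path(ws$dir, "networks", paste0(base, ".graphml")),
                 file.path(ws$dir, "networks", paste0(base, ".tsv")),
                 file.path(ws$dir, "reports", paste0(base, ".json")),
                 file.path(ws$dir, "reports", paste0(base, ".tsv")))
      export_graphml(net, paths[1]); export_edge_list(net, paths[2])
      write_screening_report(rep, paths[3]); write_screening_tsv(rep, paths[4])
      paths
    },
    align = {
      seqs <- read_fasta(p$sequences)
      aln <- star_align(seqs, match = p$match %||% 1,
                        mismatch = p$mismatch %||% -1, gap = p$gap %||% -2)
      out <- file.path(ws$dir, "alignments", paste0((p$name %||% "aln"), ".phy"))
      write_phylip(aln, out)
      out
    },
    tree = {
      aln <- read_phylip(file.path(ws$dir, "alignments",
                                   paste0((p$alignment %||% "aln"), ".phy")))
      d <- distance_matrix(aln, model = p$model %||% "jc69")
      tree <- neighbor_joining(d, clamp_negative = isTRUE(p$clamp_negative))
      out <- file.path(ws$dir, "trees", paste0((p$name %||% "tree"), ".nwk"))
      write_newick(tree, out)
      out
    },
    full = {
      rec <- run_pipeline(ws, p$config)
      unlist(rec$artifacts$path)
    },
    stop(sprintf("unknown stage '%s'", job$stage), call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_blast_any <- function(p) {
  fmt <- p$format %||% "tab"
  if (fmt == "xml") {
    if (!is.null(p$text)) parse_blast_xml(text = p$text) else parse_blast_xml(p$file)
  } else {
    if (!is.null(p$text)) parse_blast_tabular(text = p$text) else parse_blast_tabular(p$file)
  }
}

# Normalized hits as a 12-column tabular report so later stages re-read a
# uniform format regardless of the original input flavor.
.write_results_tsv <- function(results, file) {
  lines <- unlist(lapply(results, function(r) {
    h <- r$hits
    if (!nrow(h)) return(character())
    sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
            r$query_id, h$subject_id, .num_chr(h$percent_identity),
            h$align_length, rep(0L, nrow(h)), rep(0L, nrow(h)),
            h$q_start, h$q_end, h$s_start, h$s_end,
            .num_chr(h$evalue), .num_chr(h$bit_score))
  }))
  .output_lines(lines, file)
}

#' Run the staged pipeline and record provenance
#'
#' Executes collection import, BLAST parsing, network building, screening
#' (halting there when `halt_after_screening` is set), sequence selection,
#' then every configured alignment and every configured tree. Multiple
#' alignment parameter sets may share one screening report and multiple
#' tree parameter sets one alignment. Every stage writes its artifact and
#' its fully-resolved parameters (defaults included) into a permanent
#' provenance record with artifact checksums, so the run can be replicated
#' exactly.
#'
#' Config schema (all sections optional except collection and blast
#' inputs): `name`; `collection = list(file|text, format, name)`;
#' `blast = list(file|text, format)`; `network = list(max_evalue,
#' min_bit_score, min_percent_identity, max_rank, count_self)`;
#' `screening = list(min_associations, include_ids, exclude_ids)`;
#' `halt_after_screening`; `subject_db` (FASTA path; hits are reconstructed
#' from XML HSP segments when absent); `alignments = list(<name> =
#' list(match, mismatch, gap))`; `trees = list(<name> = list(alignment,
#' model, clamp_negative))`.
#'
#' @param ws a [workspace()].
#' @param config configuration list (see schema above) or the result of
#'   [read_pipeline_config()].
#' @return an object of class `provenance_record`.
#' @export
run_pipeline <- function(ws, config) {
  stopifnot(inherits(ws, "workspace"), is.list(config))
  cfg <- .resolve_config(config)
  run_id <- cfg$name
  artifacts <- data.frame(stage = character(), path = character(),
                          stringsAsFactors = FALSE)
  add_artifact <- function(stage, path) {
    artifacts <<- rbind(artifacts,
                        data.frame(stage = stage, path = path,
                                   stringsAsFactors = FALSE))
  }
  # import
  cc <- cfg$collection
  reader <- switch(cc$format, fasta = read_fasta, genbank = read_genbank,
                   raw = read_raw,
                   stop(sprintf("unknown import format '%s'", cc$format),
                        call. = FALSE))
  recs <- if (!is.null(cc$text)) reader(text = cc$text) else reader(cc$file)
  coll <- create_collection(cc$name, recs,
                            import_params = list(source_file = cc$file %||% "inline",
                                                 format = cc$format))
  coll_path <- file.path(ws$dir, "collections", paste0(run_id, ".fasta"))
  write_fasta(coll$records, coll_path)
  add_artifact("import", coll_path)
  # blast parse
  results <- .parse_blast_any(cfg$blast)
  blast_path <- file.path(ws$dir, "blast", paste0(run_id, ".tsv"))
  .write_results_tsv(results, blast_path)
  add_artifact("blast", blast_path)
  # network + screening
  nw <- cfg$network
  gate <- edge_gate(max_evalue = nw$max_evalue,
                    min_bit_score = nw$min_bit_score,
                    min_percent_identity = nw$min_percent_identity,
                    max_rank = nw$max_rank)
  net <- build_network(results, gate = gate, count_self = isTRUE(nw$count_self))
  net_paths <- file.path(ws$dir, "networks",
                         paste0(run_id, c(".graphml", ".tsv")))
  export_graphml(net, net_paths[1]); export_edge_list(net, net_paths[2])
  add_artifact("screen", net_paths[1]); add_artifact("screen", net_paths[2])
  crit <- screening_criteria(cfg$screening$min_associations, gate = gate,
                             include_ids = as.character(unlist(cfg$screening$include_ids)),
                             exclude_ids = as.character(unlist(cfg$screening$exclude_ids)))
  report <- apply_screening(net, crit)
  rep_paths <- file.path(ws$dir, "reports", paste0(run_id, c(".json", ".tsv")))
  write_screening_report(report, rep_paths[1])
  write_screening_tsv(report, rep_paths[2])
  add_artifact("screen", rep_paths[1]); add_artifact("screen", rep_paths[2])
  halted <- isTRUE(cfg$halt_after_screening)
  if (!halted) {
    subject_db <- if (!is.null(cfg$subject_db)) read_fasta(cfg$subject_db)
    seqset <- select_sequences(report, coll, subject_db = subject_db, net = net)
    sel_path <- file.path(ws$dir, "collections", paste0(run_id, "_selected.fasta"))
    write_fasta(seqset$members[names(seqset$members) != "partial"], sel_path)
    add_artifact("screen", sel_path)
    for (an in names(cfg$alignments)) {
      ap <- cfg$alignments[[an]]
      aln <- star_align(seqset, match = ap$match, mismatch = ap$mismatch,
                        gap = ap$gap)
      aln_path <- file.path(ws$dir, "alignments",
                            paste0(run_id, "_", an, ".phy"))
      write_phylip(aln, aln_path)
      add_artifact("align", aln_path)
    }
    for (tn in names(cfg$trees)) {
      tp <- cfg$trees[[tn]]
      aln_path <- file.path(ws$dir, "alignments",
                            paste0(run_id, "_", tp$alignment, ".phy"))
      if (!file.exists(aln_path)) {
        stop(sprintf("tree '%s' references unknown alignment '%s'", tn,
                     tp$alignment), call. = FALSE)
      }
      aln <- read_phylip(aln_path)
      d <- distance_matrix(aln, model = tp$model)
      tree <- neighbor_joining(d, clamp_negative = isTRUE(tp$clamp_negative))
      tree_path <- file.path(ws$dir, "trees", paste0(run_id, "_", tn, ".nwk"))
      write_newick(tree, tree_path)
      add_artifact("tree", tree_path)
      svg_path <- file.path(ws$dir, "trees", paste0(run_id, "_", tn, ".svg"))
      export_tree_svg(tree, svg_path)
      add_artifact("tree", svg_path)
    }
  }
  artifacts$checksum <- unname(tools::md5sum(artifacts$path))
  rec <- structure(list(run_id = run_id,
                        created_at = .timestamp(),
                        halted_after_screening = halted,
                        config_resolved = cfg,
                        stages = list(
                          import = cfg$collection,
                          blast = cfg$blast,
                          screen = c(cfg$network,
                                     cfg$screening,
                                     list(halt_after_screening = halted)),
                          align = if (halted) NULL else cfg$alignments,
                          tree = if (halted) NULL else cfg$trees),
                        artifacts = artifacts,
                        tools = list(package = "assocnet",
                                     version = as.character(utils::packageVersion("assocnet")),
                                     r_version = paste(R.version$major,
                                                       R.version$minor, sep = "."))),
                   class = "provenance_record")
  prov_path <- file.path(ws$dir, "provenance", paste0(run_id, ".json"))
  write_provenance(rec, prov_path)
  rec
}

#' @export
print.provenance_record <- function(x, ...) {
  cat(sprintf("<provenance_record> run '%s': %d artifact(s)%s\n", x$run_id,
              nrow(x$artifacts),
              if (x$halted_after_screening) " (halted after screening)" else ""))
  invisible(x)
}

#' Serialize a provenance record
#'
#' @param rec a `provenance_record`.
#' @param file path, connection, or `NULL` to return text invisibly.
#' @return the JSON text, invisibly.
#' @export
write_provenance <- function(rec, file = NULL) {
  stopifnot(inherits(rec, "provenance_record"))
  doc <- unclass(rec)
  doc$artifacts <- lapply(seq_len(nrow(rec$artifacts)), function(k) {
    as.list(rec$artifacts[k, ])
  })
  .output_lines(as.character(
    jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA,
                     pretty = TRUE)), file)
}

#' Replay a provenance record
#'
#' Re-runs the pipeline from the record's fully-resolved parameters. For
#' built-in stages the reproduced artifacts are byte-identical to the
#' originals (verified against the stored checksums).
#'
#' @param ws a [workspace()].
#' @param rec a `provenance_record` (or path to its JSON).
#' @param verify logical; stop if any reproduced checksum differs.
#' @return the new `provenance_record`.
#' @export
replay_run <- function(ws, rec, verify = TRUE) {
  if (.is_string(rec)) {
    doc <- jsonlite::fromJSON(rec, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    cfg <- doc$config_resolved
    old <- do.call(rbind, lapply(doc$artifacts, as.data.frame))
  } else {
    stopifnot(inherits(rec, "provenance_record"))
    cfg <- rec$config_resolved
    old <- rec$artifacts
  }
  new_rec <- run_pipeline(ws, cfg)
  if (verify) {
    m <- match(old$path, new_rec$artifacts$path)
    bad <- old$path[is.na(m) |
                    old$checksum != new_rec$artifacts$checksum[m]]
    if (length(bad)) {
      stop(sprintf("replay did not reproduce artifact(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  new_rec
}
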