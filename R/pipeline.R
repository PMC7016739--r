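#' Run the scatter-gather pipeline
#'
#' Executes the full flow with three synchronization barriers:
#'
#' 1. **Scatter**: the FASTQ input is split into chunks; one first-pass
#'    mapping task runs per chunk in parallel.
#' 2. **Barrier 1**: all chunk splice-junction tables are merged and the
#'    genome index is rebuilt once, sequentially; then second-pass mapping
#'    runs per chunk in parallel against the new index.
#' 3. **Barrier 2**: all mapped records are profiled against the static
#'    region plan (computed up front from the reference index alone), the
#'    dynamic plan refines it by observed read counts, and records are
#'    routed into per-region sorted SAM shards.
#' 4. **Fan-out**: one variant-calling task runs per dynamic region in
#'    parallel.
#' 5. **Barrier 3**: per-region VCFs are merged into the final VCF.
#'
#' Stage tools are arbitrary shell commands from the config (real
#' aligner/caller invocations, or the bundled mocks from
#' [mock_stage_commands()]). Task outputs are written under deterministic
#' shard names with an `.ok` marker on completion; with `resume = TRUE`
#' (default) a rerun after a failure skips completed tasks and produces the
#' same final VCF as a clean run. A failing stage command aborts the
#' pipeline at the current barrier with the manifest recording per-shard
#' status and all intermediates preserved.
#'
#' With deterministic stage commands the final VCF is byte-identical for a
#' fixed config regardless of worker count, and — for a strictly
#' region-local caller such as the bundled mock — regardless of `n_chunks`
#' and `num_regions` too.
#'
#' @param config a [validate_config()] result, or a path / list accepted by
#'   it.
#' @param resume reuse completed task outputs found in the workdir
#'   (default `TRUE`).
#' @return The run manifest (also written to `<workdir>/manifest.json`):
#'   per-stage status and timestamps, file inventories with record counts,
#'   realised region counts (RsLB, RdLB), and the config snapshot.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  if (!inherits(config, "PipelineConfig")) config <- validate_config(config)
  wd <- config$workdir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(wd, "manifest.json")
  manifest <- list(
    config = unclass(config),
    created = timestamp_now(),
    stages = list(),
    plan = list(),
    counts = list()
  )
  paired <- length(config$inputs) == 2L

  # static plan needs only the reference index, so it exists before any
  # mapping finishes
  ref <- load_reference_index(config$reference_index)
  splan <- static_partition(ref, config$num_regions)
  write_region_bed(splan$region_set, file.path(wd, "static.bed"))
  manifest$plan$requested <- config$num_regions
  manifest$plan$rslb <- splan$rslb
  manifest$plan$avg_size_static <- splan$avg_size_static

  # scatter: FASTQ chunks (cached as a unit)
  st <- stage_begin("split_fastq")
  chunks_json <- file.path(wd, "chunks.json")
  if (resume && file.exists(paste0(chunks_json, ".ok"))) {
    chunk_info <- jsonlite::fromJSON(chunks_json, simplifyVector = FALSE)
    chunks <- lapply(chunk_info$chunks, unlist)
    n_records <- unlist(chunk_info$n_records)
    st$status <- "cached"
  } else {
    sp <- split_fastq(config$inputs, config$n_chunks, file.path(wd, "chunks"))
    chunks <- sp$chunks
    n_records <- sp$n_records
    jsonlite::write_json(list(chunks = chunks, n_records = n_records),
                         chunks_json, auto_unbox = FALSE, digits = NA)
    file.create(paste0(chunks_json, ".ok"))
    st$status <- "done"
  }
  st$n_chunks <- length(chunks)
  manifest$stages$split_fastq <- stage_end(st)
  manifest$counts$fastq_records <- n_records[1L]

  # parallel mapping pass 1 (SAM of pass 1 is discarded; only SJ matters)
  p1_prefix <- file.path(wd, "pass1", sprintf("chunk.%04d", seq_along(chunks)))
  dir.create(file.path(wd, "pass1"), showWarnings = FALSE)
  p1_cmds <- vapply(seq_along(chunks), function(k) {
    render_command(config$stages$map_pass1, list(
      input = chunks[[k]][1L],
      input2 = if (paired) chunks[[k]][2L] else NULL,
      index = config$index, reference = config$reference,
      output = p1_prefix[k]
    ))
  }, "")
  manifest <- run_stage(manifest, manifest_path, "map_pass1", p1_cmds,
                        paste0(p1_prefix, ".SJ.out.tab"), config$workers,
                        resume)

  # barrier 1: merge splice junctions, rebuild index once (sequential)
  st <- stage_begin("merge_sj")
  sj_merged <- file.path(wd, "sj.merged.tab")
  merged <- merge_splice_junctions(paste0(p1_prefix, ".SJ.out.tab"),
                                   ref = ref, out = sj_merged)
  st$status <- "done"
  st$n_junctions <- nrow(merged)
  manifest$stages$merge_sj <- stage_end(st)

  index2 <- file.path(wd, "index2")
  rebuild_cmd <- render_command(config$stages$index_rebuild, list(
    input = sj_merged, index = config$index, reference = config$reference,
    output = index2
  ))
  manifest <- run_stage(manifest, manifest_path, "index_rebuild",
                        rebuild_cmd, index2, workers = 1L, resume)

  # parallel mapping pass 2 against the rebuilt index
  p2_prefix <- file.path(wd, "pass2", sprintf("chunk.%04d", seq_along(chunks)))
  dir.create(file.path(wd, "pass2"), showWarnings = FALSE)
  p2_cmds <- vapply(seq_along(chunks), function(k) {
    render_command(config$stages$map_pass2, list(
      input = chunks[[k]][1L],
      input2 = if (paired) chunks[[k]][2L] else NULL,
      index = index2, reference = config$reference,
      output = p2_prefix[k]
    ))
  }, "")
  manifest <- run_stage(manifest, manifest_path, "map_pass2", p2_cmds,
                        paste0(p2_prefix, ".sam"), config$workers, resume)

  # barrier 2: profile, dynamic plan, route into per-region shards
  st <- stage_begin("route")
  regions_dir <- file.path(wd, "regions")
  routing_json <- file.path(regions_dir, "routing.json")
  if (resume && file.exists(paste0(routing_json, ".ok"))) {
    routing <- jsonlite::fromJSON(routing_json, simplifyVector = TRUE)
    st$status <- "cached"
  } else {
    sams <- lapply(paste0(p2_prefix, ".sam"), read_sam_file)
    records <- do.call(rbind, lapply(sams, `[[`, "records"))
    profile <- profile_regions(records, splan)
    dplan <- dynamic_partition(profile)
    write_region_bed(dplan$region_set, file.path(wd, "dynamic.bed"))
    routed <- route_sam(records, dplan$region_set, regions_dir,
                        header = sams[[1L]]$header)
    if (sum(routed$counts) + routed$n_unmapped != nrow(records)) {
      stop("internal error: routed record count does not match input",
           call. = FALSE)
    }
    rs <- dplan$region_set
    for (r in seq_len(nrow(rs))) {
      write_region_bed(rs[r, , drop = FALSE],
                       file.path(regions_dir, sprintf("region.%04d.bed", r)))
    }
    routing <- list(rdlb = dplan$rdlb,
                    avg_size_dynamic = dplan$avg_size_dynamic,
                    mapped = profile$total_reads,
                    unmapped = profile$n_unmapped,
                    shard_counts = routed$counts)
    jsonlite::write_json(routing, routing_json, auto_unbox = TRUE,
                         digits = NA)
    file.create(paste0(routing_json, ".ok"))
    st$status <- "done"
  }
  manifest$plan$rdlb <- routing$rdlb
  manifest$plan$avg_size_dynamic <- routing$avg_size_dynamic
  manifest$counts$mapped <- routing$mapped
  manifest$counts$unmapped <- routing$unmapped
  manifest$counts$routed <- sum(routing$shard_counts)
  manifest$stages$route <- stage_end(st)
  write_manifest(manifest, manifest_path)

  # fan-out: per-region variant calling
  n_reg <- routing$rdlb
  shard <- file.path(regions_dir, sprintf("region.%04d.sam", seq_len(n_reg)))
  beds <- file.path(regions_dir, sprintf("region.%04d.bed", seq_len(n_reg)))
  vcfs <- file.path(wd, "calls", sprintf("region.%04d.vcf", seq_len(n_reg)))
  dir.create(file.path(wd, "calls"), showWarnings = FALSE)
  call_cmds <- vapply(seq_len(n_reg), function(r) {
    render_command(config$stages$per_region_call, list(
      input = shard[r], region_bed = beds[r], index = index2,
      reference = config$reference, output = vcfs[r]
    ))
  }, "")
  manifest <- run_stage(manifest, manifest_path, "per_region_call",
                        call_cmds, vcfs, config$workers, resume)

  # barrier 3: merge per-region VCFs
  st <- stage_begin("merge_vcf")
  final_vcf <- file.path(wd, "final.vcf")
  mv <- merge_vcf(vcfs, ref, final_vcf)
  st$status <- "done"
  manifest$stages$merge_vcf <- stage_end(st)
  manifest$counts$vcf_records <- mv$n_records
  manifest$counts$vcf_duplicates <- mv$n_duplicates
  manifest$final_vcf <- final_vcf
  manifest$finished <- timestamp_now()
  write_manifest(manifest, manifest_path)
  manifest
}

timestamp_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS6%z")
}

stage_begin <- function(name) {
  list(name = name, started = timestamp_now())
}

stage_end <- function(st) {
  st$finished <- timestamp_now()
  st
}

# Run one parallel stage of shell commands with .ok completion markers.
# On any failure: record per-shard status in the manifest, write it, and
# abort with a regionpipe_pipeline_error.
run_stage <- function(manifest, manifest_path, stage, cmds, outputs,
                      workers, resume) {
  st <- stage_begin(stage)
  ok_files <- paste0(outputs, ".ok")
  cached <- resume & file.exists(ok_files)
  todo <- which(!cached)
  run_one <- function(i) {
    status <- system2("sh", c("-c", shQuote(cmds[i])), stdout = FALSE,
                      stderr = FALSE)
    if (identical(status, 0L)) file.create(ok_files[i])
    status
  }
  codes <- integer(length(cmds))
  if (length(todo)) {
    res <- if (workers > 1L) {
      parallel::mclapply(todo, run_one, mc.cores = workers,
                         mc.preschedule = FALSE)
    } else {
      lapply(todo, run_one)
    }
    codes[todo] <- vapply(res, function(x) {
      if (is.integer(x) || is.numeric(x)) as.integer(x) else 1L
    }, 1L)
  }
  st$tasks <- data.frame(
    shard = seq_along(cmds),
    output = outputs,
    status = ifelse(cached, "cached",
                    ifelse(codes == 0L, "done",
                           ifelse(seq_along(cmds) %in% todo, "failed",
                                  "not_started"))),
    stringsAsFactors = FALSE
  )
  failed <- which(st$tasks$status == "failed")
  st$status <- if (length(failed)) "failed" else "done"
  manifest$stages[[stage]] <- stage_end(st)
  write_manifest(manifest, manifest_path)
  if (length(failed)) {
    stop(structure(
      class = c("regionpipe_pipeline_error", "error", "condition"),
      list(message = sprintf(
        "stage '%s' failed on shard(s) %s; intermediates preserved in place",
        stage, paste(failed, collapse = ", ")),
        call = NULL, manifest = manifest)
    ))
  }
  manifest
}

write_manifest <- function(manifest, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", force = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a pipeline run manifest
#' @param workdir the pipeline working directory (or a manifest.json path).
#' @return The manifest as a list.
#' @export
read_manifest <- function(workdir) {
  path <- if (dir.exists(workdir)) file.path(workdir, "manifest.json") else
    workdir
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
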