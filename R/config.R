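#' Validate a pipeline configuration
#'
#' Reads a YAML or JSON config (or takes an equivalent named list),
#' applies defaults, and checks it before anything runs: referenced paths
#' must exist, and every stage command template must contain the
#' placeholders the orchestrator will substitute for it.
#'
#' Fields:
#' * `reference_index` — .fai or .dict path (required).
#' * `reference` — reference FASTA path; required only when a stage
#'   template uses `{reference}`.
#' * `index` — initial genome index directory (required).
#' * `inputs` — 1 (single-end) or 2 (paired) FASTQ paths (required).
#' * `num_regions` — requested region count for the load balancer
#'   (required).
#' * `workers` — parallel worker processes (default 1).
#' * `n_chunks` — FASTQ chunk count; defaults to `workers`, one chunk per
#'   thread.
#' * `workdir` — working directory for all intermediates (required; created
#'   on run).
#' * `seed` — recorded in the manifest (default 1).
#' * `stages` — named command templates `map_pass1`, `index_rebuild`,
#'   `map_pass2`, `per_region_call`. Placeholders: `{input}`, `{input2}`,
#'   `{index}`, `{region_bed}`, `{reference}`, `{output}`. Required per
#'   stage: mapping passes need `{input}`, `{index}`, `{output}` (plus
#'   `{input2}` for paired input); `index_rebuild` needs `{input}`,
#'   `{output}`; `per_region_call` needs `{input}`, `{region_bed}`,
#'   `{output}`.
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @return A validated `PipelineConfig` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext == "json") {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  need <- function(field) {
    if (is.null(config[[field]])) {
      stop("config: missing required field '", field, "'", call. = FALSE)
    }
    config[[field]]
  }
  cfg <- list(
    reference_index = need("reference_index"),
    reference = config$reference,
    index = need("index"),
    inputs = as.character(need("inputs")),
    num_regions = as.integer(need("num_regions")),
    workers = if (is.null(config$workers)) 1L else as.integer(config$workers),
    workdir = need("workdir"),
    seed = if (is.null(config$seed)) 1L else as.integer(config$seed),
    stages = need("stages"),
    min_call_reads = config$min_call_reads
  )
  cfg$n_chunks <- if (is.null(config$n_chunks)) cfg$workers else
    as.integer(config$n_chunks)
  if (!length(cfg$inputs) %in% c(1L, 2L)) {
    stop("config: 'inputs' must list 1 or 2 FASTQ paths", call. = FALSE)
  }
  if (cfg$num_regions < 1L) stop("config: num_regions must be >= 1",
                                 call. = FALSE)
  if (cfg$workers < 1L) stop("config: workers must be >= 1", call. = FALSE)
  if (cfg$n_chunks < 1L) stop("config: n_chunks must be >= 1", call. = FALSE)
  for (p in c(cfg$reference_index, cfg$inputs, cfg$reference, cfg$index)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("config: referenced path does not exist: ", p, call. = FALSE)
    }
  }
  required_ph <- list(
    map_pass1 = c("input", "index", "output"),
    index_rebuild = c("input", "output"),
    map_pass2 = c("input", "index", "output"),
    per_region_call = c("input", "region_bed", "output")
  )
  known <- c("input", "input2", "index", "region_bed", "reference", "output")
  for (stage in names(required_ph)) {
    tpl <- cfg$stages[[stage]]
    if (is.null(tpl) || !is.character(tpl) || length(tpl) != 1L) {
      stop("config: missing stage command '", stage, "'", call. = FALSE)
    }
    found <- regmatches(tpl, gregexpr("\\{[a-z0-9_]+\\}", tpl))[[1L]]
    found <- gsub("[{}]", "", found)
    unknown <- setdiff(found, known)
    if (length(unknown)) {
      stop(sprintf("config: stage '%s' uses unknown placeholder {%s}",
                   stage, unknown[1L]), call. = FALSE)
    }
    req <- required_ph[[stage]]
    if (length(cfg$inputs) == 2L && stage %in% c("map_pass1", "map_pass2")) {
      req <- c(req, "input2")
    }
    missing <- setdiff(req, found)
    if (length(missing)) {
      stop(sprintf("config: stage '%s' template missing placeholder {%s}",
                   stage, missing[1L]), call. = FALSE)
    }
    if ("reference" %in% found && is.null(cfg$reference)) {
      stop(sprintf("config: stage '%s' uses {reference} but no 'reference' is set",
                   stage), call. = FALSE)
    }
  }
  structure(cfg, class = "PipelineConfig")
}

# Substitute placeholders into a stage command template. Values are shell
# quoted; an unsubstituted placeholder left over is an error.
render_command <- function(template, values) {
  cmd <- template
  for (nm in names(values)) {
    if (is.null(values[[nm]])) next
    cmd <- gsub(paste0("{", nm, "}"), shQuote(values[[nm]]), cmd,
                fixed = TRUE)
  }
  left <- regmatches(cmd, gregexpr("\\{[a-z0-9_]+\\}", cmd))[[1L]]
  if (length(left)) {
    stop("unsubstituted placeholder ", left[1L], " in command: ", cmd,
         call. = FALSE)
  }
  cmd
}
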