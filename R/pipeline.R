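# Raw-cohort schema columns (as written by generate_cohort)
raw_cohort_columns <- function() {
  c("respondent_id", "birth_month", "oc_csection", "oc_low_birth_weight",
    "oc_preterm", "paternal_age", "handedness", "emotional_neglect",
    "emotional_abuse", "bullying", "sexual_abuse",
    sprintf("cpq_%02d", 1:11), "residence",
    "pq16", "gad7", "phq9", "mdq", "ocir", "asrs5",
    "age", "gender", "education", "employment", "es")
}

#' Default network variable specification
#'
#' The 11 default network nodes: the exposome score, the six symptom
#' sum-scores and age as continuous nodes; education (higher vs. other),
#' gender (male vs. female) and employment (employed vs. unemployed) as
#' binary nodes.
#'
#' @return Named character vector of node types.
#' @export
default_variable_spec <- function() {
  c(es = "continuous", phq9 = "continuous", gad7 = "continuous",
    mdq = "continuous", asrs5 = "continuous", pq16 = "continuous",
    ocir = "continuous", age = "continuous", education = "binary",
    gender = "binary", employment = "binary")
}

# dichotomizations applied to character covariate columns when they enter
# the network as binary nodes
binary_codings <- function() {
  list(gender = "male",
       education = "higher",
       employment = c("full_time", "part_time"))
}

#' Read a cohort CSV and build the typed network dataset
#'
#' Reads a raw (or scored) cohort CSV with empty strings as missing cells,
#' warns about and ignores unknown columns, applies the standard
#' dichotomizations to character covariates, and drops rows with missing
#' network variables (listwise deletion, with the dropped count reported).
#' Obstetric "I don't know" answers are preserved verbatim as a level (they
#' become missing only at binarization).
#'
#' @param path CSV path (header row; missing cell = empty string).
#' @param variable_spec Named node-type vector (default
#'   [default_variable_spec()]); node columns absent from the file are
#'   dropped from the network with a warning.
#' @return List: `raw` (the as-read table), `mixed` (a [mixed_data()] of
#'   complete cases over the node columns, or `NULL` if fewer than two node
#'   columns are present), `n_dropped` (rows lost to listwise deletion).
#' @export
read_cohort <- function(path, variable_spec = default_variable_spec()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    read.csv(path, na.strings = "", stringsAsFactors = FALSE,
             check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    stop("empty cohort file: ", path, call. = FALSE)
  }
  known <- union(raw_cohort_columns(), names(variable_spec))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  nodes <- intersect(names(variable_spec), names(raw))
  absent <- setdiff(names(variable_spec), names(raw))
  if (length(absent)) {
    warning("node column(s) not in file, excluded from network: ",
            paste(absent, collapse = ", "))
  }
  mixed <- NULL
  n_dropped <- 0L
  if (length(nodes) >= 2) {
    codings <- binary_codings()
    mat <- sapply(nodes, function(nd) {
      col <- raw[[nd]]
      if (variable_spec[[nd]] == "binary" && is.character(col)) {
        if (!nd %in% names(codings)) {
          stop("no dichotomization rule for character column ", nd,
               call. = FALSE)
        }
        as.numeric(col %in% codings[[nd]]) + ifelse(is.na(col), NA, 0)
      } else {
        v <- suppressWarnings(as.numeric(col))
        if (any(is.na(v) & !is.na(col))) {
          bad <- which(is.na(v) & !is.na(col))[1]
          stop("cannot coerce row ", bad, ", column ", nd, " to numeric",
               call. = FALSE)
        }
        v
      }
    })
    mat <- matrix(as.numeric(mat), nrow = nrow(raw),
                  dimnames = list(NULL, nodes))
    keep <- complete.cases(mat)
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      message(n_dropped, " row(s) dropped by listwise deletion over ",
              "network variables")
    }
    if (sum(keep) > length(nodes)) {
      mixed <- mixed_data(mat[keep, , drop = FALSE],
                          unname(variable_spec[nodes]))
    }
  }
  list(raw = raw, mixed = mixed, n_dropped = n_dropped)
}

#' Write a cohort CSV
#'
#' One row per respondent, header row, UTF-8, missing cells written as
#' empty strings.
#'
#' @param cohort Data frame.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "", quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an edge list CSV
#'
#' All node pairs with edge magnitude and sign (`+`, `-`, `undefined` for
#' conflicting coefficient signs, `0` for absent edges).
#'
#' @param network A `pairwise_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  nodes <- network$nodes
  p <- length(nodes)
  rows <- list()
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      w <- network$weights[j, k]
      s <- network$signs[j, k]
      sign_chr <- if (w == 0) "0" else if (is.na(s)) "undefined"
      else if (s >= 0) "+" else "-"
      rows[[length(rows) + 1]] <- data.frame(
        node_i = nodes[j], node_j = nodes[k], weight = w, sign = sign_chr,
        stringsAsFactors = FALSE)
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the dense edge-weight matrix CSV
#'
#' @param network A `pairwise_network`.
#' @param path Output path.
#' @export
write_edge_matrix <- function(network, path) {
  df <- data.frame(node = network$nodes, network$weights,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML
#'
#' Hands the weighted undirected graph (non-zero edges only, node type and
#' predictability as attributes) to visualization tools.
#'
#' @param network A `pairwise_network`.
#' @param path Output path.
#' @export
export_graphml <- function(network, path) {
  g <- igraph::graph_from_adjacency_matrix(signed_weights(network),
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(network$types)) {
    igraph::V(g)$type <- unname(network$types[network$nodes])
  }
  pr <- network$predictability
  if (!is.null(pr)) igraph::V(g)$predictability <- unname(pr[network$nodes])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# 32-bit FNV-1a over a string; used for the manifest config hash
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

default_pipeline_config <- function() {
  list(
    cohort = list(n = 1100, seed = 1),
    input_csv = NULL,
    edge_matrix_csv = NULL,
    weights_path = NULL,
    denominator_policy = "fixed_total",
    network = list(variable_spec = as.list(default_variable_spec()),
                   gamma = 0.25, rule = "AND", nlambda = 50,
                   lambda_min_ratio = 0.01),
    bootstrap = list(enabled = FALSE, B = 1000,
                     proportions = seq(0.05, 0.75, by = 0.05)),
    stages = c("simulate", "score", "estimate", "bootstrap", "report"),
    output_dir = "exponet_run",
    seed = 1,
    log_level = "info"
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration
#'
#' Loads a YAML configuration (or accepts a list) and merges it over the
#' defaults. Recognised blocks: `cohort` (n, seed, prevalences,
#' symptom_marginals, missingness), `input_csv`, `edge_matrix_csv`,
#' `weights_path`, `denominator_policy`, `network` (variable_spec, gamma,
#' rule, nlambda, lambda_min_ratio), `bootstrap` (enabled, B, proportions),
#' `stages`, `output_dir`, `seed`, `log_level`.
#'
#' @param config YAML path or list.
#' @return Config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  merge_config(default_pipeline_config(), config)
}

log_msg <- function(level, ..., log_level = "info") {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[log_level]]) {
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> score -> estimate -> bootstrap -> report.
#' Writes, under `output_dir`: the simulated cohort CSV (if simulated),
#' per-respondent exposome scores, the edge list and dense edge-matrix
#' CSVs, predictability CSV, the centrality report JSON, stability JSON
#' (when bootstrapping), a GraphML export, and a run manifest (config hash,
#' seed, package version, per-stage status). Re-running with the same
#' config and seed reproduces byte-identical numeric outputs. With an
#' `edge_matrix_csv` input and the `report` stage only, summarizes the
#' provided network instead of estimating one.
#'
#' @param config Config list or YAML path (see [read_pipeline_config()]).
#' @return Invisibly, a list with output `paths` and the `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  lv <- cfg$log_level
  paths <- list()
  manifest <- list(
    config_hash = fnv1a_hash(as.character(jsonlite::toJSON(cfg, digits = NA,
                                                           auto_unbox = TRUE,
                                                           null = "null"))),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("exponet")),
    stages = list()
  )
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(e))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stages <- cfg$stages

  cohort <- NULL
  mixed <- NULL
  net <- NULL

  if ("simulate" %in% stages && is.null(cfg$input_csv)) {
    tryCatch({
      log_msg("info", "simulating cohort (n = ", cfg$cohort$n, ")",
              log_level = lv)
      spec_args <- list(n_respondents = cfg$cohort$n,
                        seed = if (!is.null(cfg$cohort$seed)) cfg$cohort$seed
                        else cfg$seed)
      if (!is.null(cfg$cohort$prevalences)) {
        spec_args$exposure_prevalences <- unlist(cfg$cohort$prevalences)
      }
      if (!is.null(cfg$cohort$missingness)) {
        spec_args$missingness <- unlist(cfg$cohort$missingness)
      }
      if (!is.null(cfg$cohort$symptom_marginals)) {
        sm <- cfg$cohort$symptom_marginals
        spec_args$symptom_marginals <-
          if (is.data.frame(sm)) sm else do.call(rbind, lapply(sm, as.data.frame))
      }
      cohort <- generate_cohort(do.call(cohort_spec, spec_args))
      paths$cohort <- file.path(cfg$output_dir, "cohort.csv")
      write_cohort(cohort, paths$cohort)
      manifest$stages$simulate <- list(status = "ok", n = nrow(cohort))
    }, error = function(e) fail("simulate", e))
  } else if (!is.null(cfg$input_csv)) {
    cohort <- read_cohort(cfg$input_csv)$raw
  }

  if ("score" %in% stages && !is.null(cohort)) {
    tryCatch({
      log_msg("info", "scoring exposome", log_level = lv)
      weights <- if (is.null(cfg$weights_path)) default_weight_table()
      else default_weight_table(cfg$weights_path)
      es <- score_cohort(cohort, weights, cfg$denominator_policy)
      cohort$es <- es$score
      paths$es <- file.path(cfg$output_dir, "es_scores.csv")
      write.csv(es, paths$es, row.names = FALSE)
      manifest$stages$score <- list(status = "ok",
                                    mean_es = mean(es$score, na.rm = TRUE))
    }, error = function(e) fail("score", e))
  }

  if ("estimate" %in% stages && !is.null(cohort)) {
    tryCatch({
      log_msg("info", "estimating network", log_level = lv)
      vs <- unlist(cfg$network$variable_spec)
      tmp <- tempfile(fileext = ".csv")
      write_cohort(cohort, tmp)
      rc <- read_cohort(tmp, vs)
      unlink(tmp)
      mixed <- rc$mixed
      if (is.null(mixed)) stop("no usable network dataset")
      net <- estimate_network(mixed, gamma = cfg$network$gamma,
                              rule = cfg$network$rule,
                              nlambda = cfg$network$nlambda,
                              lambda_min_ratio = cfg$network$lambda_min_ratio)
      paths$edge_list <- file.path(cfg$output_dir, "edge_list.csv")
      write_edge_list(net, paths$edge_list)
      paths$edge_matrix <- file.path(cfg$output_dir, "edge_matrix.csv")
      write_edge_matrix(net, paths$edge_matrix)
      paths$predictability <- file.path(cfg$output_dir, "predictability.csv")
      write.csv(data.frame(node = net$nodes,
                           predictability = unname(net$predictability)),
                paths$predictability, row.names = FALSE)
      paths$graphml <- file.path(cfg$output_dir, "network.graphml")
      export_graphml(net, paths$graphml)
      manifest$stages$estimate <- list(status = "ok",
                                       n_rows = nrow(mixed$values),
                                       n_dropped = rc$n_dropped)
    }, error = function(e) fail("estimate", e))
  }

  if ("bootstrap" %in% stages && isTRUE(cfg$bootstrap$enabled) &&
      !is.null(mixed)) {
    tryCatch({
      log_msg("info", "bootstrapping (B = ", cfg$bootstrap$B, ")",
              log_level = lv)
      np <- nonparametric_boot(mixed, B = cfg$bootstrap$B, seed = cfg$seed,
                               gamma = cfg$network$gamma,
                               rule = cfg$network$rule,
                               nlambda = cfg$network$nlambda,
                               lambda_min_ratio = cfg$network$lambda_min_ratio)
      qs <- t(apply(np$edges, 2, function(col) {
        col <- col[!is.na(col)]
        if (!length(col)) return(c(NA, NA, NA))
        quantile(col, c(0.025, 0.5, 0.975), names = FALSE)
      }))
      paths$edge_quantiles <- file.path(cfg$output_dir, "edge_quantiles.csv")
      write.csv(data.frame(edge = colnames(np$edges), q025 = qs[, 1],
                           q500 = qs[, 2], q975 = qs[, 3]),
                paths$edge_quantiles, row.names = FALSE)
      cd <- casedrop_boot(mixed, proportions = unlist(cfg$bootstrap$proportions),
                          B = cfg$bootstrap$B, seed = cfg$seed,
                          gamma = cfg$network$gamma, rule = cfg$network$rule,
                          nlambda = cfg$network$nlambda,
                          lambda_min_ratio = cfg$network$lambda_min_ratio)
      stab <- cs_coefficient(cd)
      paths$stability <- file.path(cfg$output_dir, "stability.json")
      jsonlite::write_json(
        list(cs_coefficient = stab$cs_coefficient,
             correlation_threshold = stab$correlation_threshold,
             probability_level = stab$probability_level,
             exceeds_0.25 = stab$exceeds_0.25,
             per_proportion = stab$per_proportion),
        paths$stability, auto_unbox = TRUE, digits = NA)
      manifest$stages$bootstrap <- list(status = "ok", B = cfg$bootstrap$B,
                                        cs_coefficient = stab$cs_coefficient)
    }, error = function(e) fail("bootstrap", e))
  }

  if ("report" %in% stages) {
    tryCatch({
      target <- if (!is.null(cfg$edge_matrix_csv)) {
        read_edge_matrix(cfg$edge_matrix_csv)
      } else net
      if (!is.null(target)) {
        rep <- network_summary(target)
        paths$centrality <- file.path(cfg$output_dir, "centrality.json")
        write_centrality_report(rep, paths$centrality)
        manifest$stages$report <- list(status = "ok",
                                       edge_count = rep$edge_count,
                                       possible_edges = rep$possible_edges)
      }
    }, error = function(e) fail("report", e))
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths$manifest <- manifest_path
  invisible(list(paths = paths, manifest = manifest))
}
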