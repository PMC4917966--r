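# Run configuration, fixture generation and report writing: the plumbing
# that ties the modules into reproducible runs.

config_schema <- function() {
  list(
    model = c("source", "preset", "structure_file", "segment_table",
              "overrides"),
    variant = NULL,
    membrane = c("inner_radius", "outer_radius", "rest_thickness",
                 "areal_modulus", "head_width", "interface_width",
                 "boundary_layer"),
    vdw = c("a_h", "d0", "cutoff", "exponents", "youngs_modulus",
            "taper_start"),
    solver = setdiff(names(formals(solver_config)), "..."),
    output_dir = NULL,
    log_level = NULL)
}

#' Parse a run configuration file
#'
#' Reads a YAML run configuration, validates it against the documented
#' schema (unknown keys are an error naming them), resolves all defaults
#' and returns a fully populated configuration. Sections: `model` (source
#' `"idealized"` with `preset`/`overrides`, or `"structure"` with
#' `structure_file` and optional `segment_table`), `variant` (WT, dNTERM,
#' +2G, +5G), `membrane`, `vdw`, `solver`, `output_dir`, `log_level`.
#'
#' @param path path to a YAML file, or a list already in config shape.
#' @return object of class `run_config` with all defaults resolved.
#' @export
parse_config <- function(path) {
  raw <- if (is.list(path)) path
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(schema)) {
    if (!is.null(schema[[sec]]) && !is.null(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), schema[[sec]])
      if (length(bad) > 0L)
        stop(sprintf("unknown key(s) under '%s': %s", sec,
                     paste(bad, collapse = ", ")))
    }
  }
  model <- raw$model %||% list()
  source <- model$source %||% "idealized"
  if (!source %in% c("idealized", "structure"))
    stop("model$source must be 'idealized' or 'structure'")
  if (source == "structure") {
    if (is.null(model$structure_file))
      stop("model$source = 'structure' requires model$structure_file")
    if (!file.exists(model$structure_file))
      stop("structure file does not exist: ", model$structure_file)
  }
  variant <- raw$variant %||% "WT"
  variant <- match.arg(variant, c("WT", "dNTERM", "+2G", "+5G"))
  params <- do.call(idealized_params,
                    c(list(preset = model$preset %||% "gating"),
                      model$overrides %||% list()))
  patch <- do.call(bilayer_patch, raw$membrane %||% list())
  law <- do.call(vdw_law, raw$vdw %||% list())
  solver <- do.call(solver_config, raw$solver %||% list())
  structure(list(model_source = source,
                 structure_file = model$structure_file,
                 segment_table = model$segment_table,
                 params = params, variant = variant,
                 patch = patch, law = law, solver = solver,
                 output_dir = raw$output_dir %||% ".",
                 log_level = raw$log_level %||% "info",
                 raw = raw),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a run configuration
#'
#' Writes the raw configuration (with every resolved default echoed back)
#' as YAML, so a run is reproducible from its echoed configuration alone.
#'
#' @param config a `run_config`.
#' @param path output file; if NULL the YAML text is returned.
#' @return the YAML text, invisibly when written to a file.
#' @export
serialize_config <- function(config, path = NULL) {
  out <- list(
    model = list(source = config$model_source,
                 preset = config$params$preset,
                 structure_file = config$structure_file,
                 segment_table = config$segment_table),
    variant = config$variant,
    membrane = config$patch[setdiff(names(config$patch), "sigma_star")],
    vdw = config$law[c("a_h", "d0", "cutoff", "exponents",
                       "youngs_modulus", "taper_start")],
    solver = config$solver[setdiff(names(unclass(config$solver)),
                                   c("loop_table", "stiffness_ratio"))],
    output_dir = config$output_dir,
    log_level = config$log_level)
  out$solver$stiffness_ratio <- as.list(config$solver$stiffness_ratio)
  out <- rapply(out, unclass, how = "replace")
  txt <- yaml::as.yaml(out)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Generate input fixtures
#'
#' Writes deterministic fixture files standing in for external inputs: an
#' idealized-geometry C-alpha PDB (`"idealized_pdb"`), a synthetic
#' lipid-helix energy-distance table (`"energy_table"`), or the bundled
#' MscL N-terminal sequence set as FASTA (`"sequences"`). The same seed
#' always produces byte-identical files.
#'
#' @param kind fixture kind.
#' @param path output file path.
#' @param seed integer seed for any noise (default 1).
#' @param params an `idealized_params` set for `"idealized_pdb"`.
#' @param law a `vdw_law` for `"energy_table"`.
#' @param noise_sd multiplicative noise of the energy table (default 0).
#' @param helix_radius C-alpha helical radius of the written backbone
#'   (default 2.3 A; 0 writes a collinear axis trace).
#' @return the output path, invisibly.
#' @export
generate_fixture <- function(kind = c("idealized_pdb", "energy_table",
                                      "sequences"),
                             path, seed = 1,
                             params = idealized_params(),
                             law = vdw_law(), noise_sd = 0,
                             helix_radius = 2.3) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "idealized_pdb") {
    model <- build_idealized(params)
    write_model_pdb(model, path, helix_radius = helix_radius)
  } else if (kind == "energy_table") {
    tab <- synthetic_energy_table(law, noise_sd = noise_sd)
    utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  } else {
    seqs <- mscl_nterm_sequences()
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(seqs))
      writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  invisible(path)
}

#' Write a channel model as a C-alpha PDB file
#'
#' Realizes each rod segment as an ideal alpha-helix C-alpha trace
#' (100 degrees per residue, 1.5 A rise) wound about its axis and writes a
#' single-model PDB with chains A-E, one chain per subunit. Reading the
#' file back through [build_from_structure()] reproduces the generating
#' geometry to within the helix-fit tolerance.
#'
#' @param model a `channel_model`.
#' @param path output PDB path.
#' @param helix_radius C-alpha radius about the axis (0 = collinear trace).
#' @return the path, invisibly.
#' @export
write_model_pdb <- function(model, path, helix_radius = 2.3) {
  xyz <- NULL; resno <- integer(0); chain <- character(0)
  chains <- LETTERS[1:5]
  ord <- order(vapply(model$helices, function(s) s$subunit_index * 1000 +
                        s$residue_range[1L], numeric(1L)))
  for (seg in model$helices[ord]) {
    n_res <- seg$residue_range[2L] - seg$residue_range[1L] + 1L
    ends <- segment_ends(seg)
    pts <- ideal_helix_coords(n_res, axis_point = ends$n,
                              axis_direction = seg$axis_direction,
                              radius = helix_radius,
                              rise = seg$length / max(n_res - 1L, 1L))
    xyz <- rbind(xyz, pts)
    resno <- c(resno, seq(seg$residue_range[1L], seg$residue_range[2L]))
    chain <- c(chain, rep(chains[seg$subunit_index + 1L], n_res))
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)), resno = resno,
                   chain = chain, resid = rep("ALA", length(resno)),
                   elety = rep("CA", length(resno)))
  invisible(path)
}

#' Export a trajectory and its gating report
#'
#' Writes the per-increment gating report as CSV and JSON, plus a summary
#' JSON (configuration echo, package version, wall time) into `outdir`.
#'
#' @param traj a `gating_trajectory`.
#' @param outdir output directory (created if missing).
#' @param prefix filename prefix (default "run").
#' @param config optional `run_config` to echo into the summary.
#' @param wall_time optional elapsed seconds to record.
#' @return named list of the files written, invisibly.
#' @export
export_trajectory <- function(traj, outdir, prefix = "run", config = NULL,
                              wall_time = NA_real_) {
  if (length(traj$states) == 0L) stop("empty trajectory")
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create directory ", outdir)
  }
  rep <- gating_report(traj)
  f_csv <- file.path(outdir, paste0(prefix, "_report.csv"))
  f_json <- file.path(outdir, paste0(prefix, "_report.json"))
  f_sum <- file.path(outdir, paste0(prefix, "_summary.json"))
  utils::write.csv(rep, f_csv, row.names = FALSE)
  jsonlite::write_json(rep, f_json, dataframe = "rows", digits = NA)
  summary <- list(
    package = "rodgate",
    version = as.character(utils::packageVersion("rodgate")),
    completed = traj$completed,
    diagnostic = traj$diagnostic,
    n_states = length(traj$states),
    sigma_final = traj$states[[length(traj$states)]]$sigma,
    wall_time_s = wall_time,
    config = if (!is.null(config)) yaml::yaml.load(serialize_config(config))
             else NULL)
  jsonlite::write_json(summary, f_sum, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(report_csv = f_csv, report_json = f_json,
                 summary_json = f_sum))
}
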