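#' Read and validate a run configuration
#'
#' YAML (or JSON) run configuration driving the command-line interface.
#' Recognized blocks: `array` (shape geometry `C`/`S`/`T`/`R` or a full
#' spec), `field` (`bx_gauss`, `bz_gauss`, `sense`), `particle`
#' (`type`: monomer/dimer, `diameter_um`, `susceptibility`), `sweep`
#' (`min_hz`, `max_hz`, `step_hz`), `frequency_hz`, `grid_step_um`,
#' `seed`, `out_dir`. Lengths are micrometers, fields gauss; everything is
#' converted to SI internally.
#'
#' @param path Config file path (.yaml/.yml/.json), or a list already in
#'   config shape.
#' @return A validated `nlm_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unrecognized config extension: ", path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A raw config list.
#' @export
validate_run_config <- function(cfg) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  array <- tryCatch({
    a <- cfg$array
    if (is.null(a)) a <- list(geometry = "C")
    if (!is.null(a$geometry)) {
      if (!a$geometry %in% c("C", "S", "T", "R"))
        note("array.geometry must be one of C, S, T, R")
      default_array(a$geometry,
                    n_x = if (is.null(a$n_x)) 11 else a$n_x,
                    n_y = if (is.null(a$n_y)) 11 else a$n_y)
    } else {
      shape <- shape_spec(a$shape$kind, unlist(a$shape$size_um),
                          if (is.null(a$shape$thickness_nm)) 100 else a$shape$thickness_nm)
      array_spec(shape, a$pitch_x_um,
                 if (is.null(a$pitch_y_um)) a$pitch_x_um else a$pitch_y_um,
                 if (is.null(a$n_x)) 11 else a$n_x,
                 if (is.null(a$n_y)) 11 else a$n_y,
                 if (is.null(a$magnetization_A_m)) 80e3 else a$magnetization_A_m,
                 if (is.null(a$glass_nm)) 600 else a$glass_nm)
    }
  }, error = function(e) { note(paste("array:", conditionMessage(e))); NULL })

  fld <- cfg$field
  ext <- tryCatch(
    external_field(bx = if (is.null(fld$bx_gauss)) 30 else fld$bx_gauss,
                   bz = if (is.null(fld$bz_gauss)) 35 else fld$bz_gauss,
                   sense = if (is.null(fld$sense)) 1 else fld$sense),
    error = function(e) { note(paste("field:", conditionMessage(e))); NULL })

  pt <- cfg$particle
  particle <- tryCatch({
    b <- bead_spec(
      diameter_um = if (is.null(pt$diameter_um)) 2.8 else pt$diameter_um,
      susceptibility = if (is.null(pt$susceptibility)) 0.7 else pt$susceptibility)
    type <- if (is.null(pt$type)) "monomer" else pt$type
    if (!type %in% c("monomer", "dimer")) note("particle.type must be monomer or dimer")
    if (identical(type, "dimer")) dimer_spec(b) else b
  }, error = function(e) { note(paste("particle:", conditionMessage(e))); NULL })

  sweep <- cfg$sweep
  freqs <- if (!is.null(sweep)) {
    if (is.null(sweep$min_hz) || is.null(sweep$max_hz))
      note("sweep needs min_hz and max_hz")
    else seq(sweep$min_hz, sweep$max_hz,
             by = if (is.null(sweep$step_hz)) (sweep$max_hz - sweep$min_hz) / 10
                  else sweep$step_hz)
  } else NULL

  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  if (is.na(seed)) note("seed must be an integer")

  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))

  structure(list(
    array = array, ext = ext, particle = particle, freqs_hz = freqs,
    frequency_hz = if (is.null(cfg$frequency_hz)) 10 else cfg$frequency_hz,
    grid_step_um = if (is.null(cfg$grid_step_um)) 0.1 else cfg$grid_step_um,
    n_particles = if (is.null(cfg$n_particles)) 40 else cfg$n_particles,
    dimer_fraction = if (is.null(cfg$dimer_fraction)) 0.3 else cfg$dimer_fraction,
    stick_prob = if (is.null(cfg$stick_prob)) 0 else cfg$stick_prob,
    seed = seed,
    out_dir = if (is.null(cfg$out_dir)) "." else cfg$out_dir,
    raw = cfg), class = "nlm_config")
}

# provenance block embedded in every output artifact
.provenance <- function(config, extra = list()) {
  c(list(package = "nlmag",
         version = as.character(packageVersion("nlmag")),
         seed = config$seed,
         config = config$raw),
    extra)
}

#' Run a pipeline command
#'
#' Dispatcher behind the command-line interface. All commands are
#' deterministic for a fixed config and seed, and every output artifact
#' embeds a provenance block (package version, seed, full config echo)
#' sufficient to regenerate it.
#'
#' * `landscape`: flux-density landscapes at phases 0, -90, -180, -270
#'   degrees (CSV each + provenance JSON).
#' * `profile`: simulated velocity-frequency profile over the sweep (CSV).
#' * `simulate`: single-particle trajectory at `frequency_hz` (CSV).
#' * `characteristics`: f_c, f_i and Omega from a closed-form or supplied
#'   profile CSV (JSON).
#' * `separate`: synthetic population through the separation protocol
#'   (JSON).
#' * `assay-stats`: dose-response table with Wilson intervals from a count
#'   CSV (JSON).
#'
#' @param name Command name (see above).
#' @param config An `nlm_config` (or path/list accepted by
#'   [read_run_config()]).
#' @param input Input file for `characteristics` (profile CSV) and
#'   `assay-stats` (count CSV); defaults to a bundled fixture for
#'   `assay-stats` and a closed-form profile for `characteristics`.
#' @return Invisibly, a character vector of the files written.
#' @export
run_command <- function(name = c("landscape", "profile", "simulate",
                                 "characteristics", "separate", "assay-stats"),
                        config, input = NULL) {
  name <- match.arg(name)
  if (!inherits(config, "nlm_config")) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  written <- character(0)
  emit_json <- function(obj, f) {
    jsonlite::write_json(obj, out(f), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <<- c(written, out(f))
  }

  if (name == "landscape") {
    for (th in c(0, -90, -180, -270)) {
      ls <- compute_landscape(config$array, config$ext, th,
                              grid_step_um = config$grid_step_um)
      f <- sprintf("landscape_theta%+04d.csv", th)
      write_landscape_csv(ls, out(f))
      written <- c(written, out(f))
    }
    emit_json(.provenance(config, list(command = "landscape",
                                       phases_deg = c(0, -90, -180, -270))),
              "landscape_provenance.json")
  } else if (name == "profile") {
    if (is.null(config$freqs_hz)) stop("profile command needs a sweep block")
    prof <- velocity_vs_frequency(config$particle, config$array, config$ext,
                                  config$freqs_hz,
                                  grid_step_um = config$grid_step_um)
    prof$provenance_seed <- config$seed
    write_profile_csv(prof, out("velocity_profile.csv"))
    written <- c(written, out("velocity_profile.csv"))
    emit_json(.provenance(config, list(command = "profile")),
              "profile_provenance.json")
  } else if (name == "simulate") {
    tr <- simulate_transport(config$particle, config$array, config$ext,
                             config$frequency_hz,
                             grid_step_um = config$grid_step_um)
    d <- as.data.frame(tr)
    write.csv(d, out("trajectory.csv"), row.names = FALSE)
    written <- c(written, out("trajectory.csv"))
    emit_json(.provenance(config, list(command = "simulate",
                                       v_mean_um_s = attr(tr, "v_mean_um_s"))),
              "trajectory_provenance.json")
  } else if (name == "characteristics") {
    prof <- if (!is.null(input)) {
      p <- read.csv(input)
      structure(p, d_um = config$array$pitch_x_um,
                class = c("nlm_vprofile", "data.frame"))
    } else {
      closed_form_profile(seq(1, 8 * config$frequency_hz, length.out = 120),
                          config$frequency_hz, config$array$pitch_x_um)
    }
    ch <- profile_characteristics(prof, config$array$pitch_x_um)
    emit_json(c(list(fc_hz = ch$fc_hz, fi_hz = ch$fi_hz, omega = ch$omega),
                .provenance(config, list(command = "characteristics"))),
              "characteristics.json")
  } else if (name == "separate") {
    pop <- synth_population(config$n_particles, config$dimer_fraction,
                            config$stick_prob, seed = config$seed,
                            array = config$array, ext = config$ext)
    mono_fc <- as.numeric(simulated_critical_frequency(
      bead_spec(), config$array, config$ext, grid_step_um = config$grid_step_um))
    dim_fc <- as.numeric(simulated_critical_frequency(
      dimer_spec(), config$array, config$ext, grid_step_um = config$grid_step_um))
    sched <- design_schedule(frequency_characteristics(mono_fc, 5.05 * mono_fc),
                             frequency_characteristics(dim_fc, 5.05 * dim_fc),
                             config$array)
    sep <- separation_protocol(pop, config$array, config$ext, sched,
                               grid_step_um = config$grid_step_um)
    emit_json(c(list(f_sb = sep$f_sb, f_agg = sep$f_agg,
                     efficiency = sep$efficiency,
                     n_monomer = sep$n_monomer, n_dimer = sep$n_dimer),
                .provenance(config, list(command = "separate"))),
              "separation.json")
  } else if (name == "assay-stats") {
    counts <- if (!is.null(input)) {
      d <- read.csv(input)
      assay_counts(d$label, d$concentration_mol_dm3, d$n_total, d$n_aggregate)
    } else load_assay_fixture("bbsa")
    dr <- dose_response(counts)
    emit_json(c(list(dose_response = as.data.frame(dr)),
                .provenance(config, list(command = "assay-stats"))),
              "dose_response.json")
  }
  invisible(written)
}
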