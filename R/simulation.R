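`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' Assembles and validates the full configuration of a healing run. All
#' defaults are the study conditions: 2 N ramp load at 1.1 N/s, one-day
#' iterations over 20 weeks (140 days), default production rate 0.02/day
#' (bone 0.012/day), 50% inflammatory baseline over the first 5 days, cell
#' infiltration calibrated to reach 95% mean callus density at day 14,
#' angiogenesis and oxygen diffusivity factors 0.5, consumption C = 0.5,
#' angiogenesis strain gate A-OSS = 6%, vessel maturation at 90%.
#'
#' @param geometry A [geometry_params()] or list of overrides.
#' @param material A [material_parameters()] or list of overrides.
#' @param protocol A [load_protocol()] or list of overrides.
#' @param rule_set Rule set name (see [rule_set()]) or a `rule_set` object.
#' @param endo An [endo_gate_params()] (used when `rule_set` is PE-ENDO).
#' @param rates List with `default` (fraction/day, tendon/cartilage/fat)
#'   and `bone`.
#' @param inflammatory List with `days` and `fraction`.
#' @param tendon_law List with `peak_strain` and `zero_strain` (percent)
#'   for the strain-dependent tendon production law.
#' @param transport List with `D_cells` (mm^2/day; `NULL` means calibrate),
#'   `A` (relative factor on the calibrated cell diffusivity: vessel fronts
#'   co-migrate with the granulation tissue), `O` (relative factor on
#'   `O_unit`), `O_unit` (mm^2/day; the default 0.0225 sets the Krogh-type
#'   oxygen penetration length `sqrt(O * O_unit / C)` to 0.15 mm at the
#'   default factors, the physiologic diffusion distance from a capillary,
#'   so oxygenation is vessel-limited), `C` (consumption, 1/day at full
#'   cell density), `a_oss` (percent), `maturation` (fraction).
#' @param reorientation List with `enabled`, `total_days`, `n_fibrils`.
#' @param callus_tendon Initial callus tendon-like density fraction.
#' @param horizon Number of daily iterations (140 = 20 weeks).
#' @param dt Iteration length in days.
#' @param seed RNG seed (consumed only by fibril initialization).
#' @param snapshot_every Store full field snapshots every this many days
#'   (0 = none; the final state is always kept).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = geometry_params(),
                              material = material_parameters(),
                              protocol = load_protocol(),
                              rule_set = "PE",
                              endo = endo_gate_params(),
                              rates = list(default = 0.02, bone = 0.012),
                              inflammatory = list(days = 5, fraction = 0.5),
                              tendon_law = list(peak_strain = 15,
                                                zero_strain = 30),
                              transport = list(D_cells = NULL, A = 0.5,
                                               O = 0.5, O_unit = 0.0225,
                                               C = 0.5, a_oss = 6,
                                               maturation = 0.90),
                              reorientation = list(enabled = TRUE,
                                                   total_days = 28,
                                                   n_fibrils = 13L),
                              callus_tendon = 0.10,
                              horizon = 140L, dt = 1, seed = 1L,
                              snapshot_every = 0L) {
  defaults <- formals(simulation_config)
  fill <- function(x, def) utils::modifyList(eval(def), as.list(x))
  if (!inherits(geometry, "geometry_params"))
    geometry <- do.call(geometry_params, as.list(geometry))
  if (!inherits(material, "material_parameters"))
    material <- do.call(material_parameters, as.list(material))
  if (!inherits(protocol, "load_protocol"))
    protocol <- do.call(load_protocol, as.list(protocol))
  if (!inherits(endo, "endo_gate_params"))
    endo <- do.call(endo_gate_params, as.list(endo))
  rates <- fill(rates, defaults$rates)
  inflammatory <- fill(inflammatory, defaults$inflammatory)
  tendon_law <- fill(tendon_law, defaults$tendon_law)
  transport <- utils::modifyList(
    list(D_cells = NULL, A = 0.5, O = 0.5, O_unit = 0.0225, C = 0.5,
         a_oss = 6, maturation = 0.90),
    as.list(transport))
  reorientation <- fill(reorientation, defaults$reorientation)

  cfg <- structure(list(geometry = geometry, material = material,
                        protocol = protocol, rule_set = rule_set,
                        endo = endo, rates = rates,
                        inflammatory = inflammatory,
                        tendon_law = tendon_law, transport = transport,
                        reorientation = reorientation,
                        callus_tendon = callus_tendon,
                        horizon = as.integer(horizon), dt = dt,
                        seed = as.integer(seed),
                        snapshot_every = as.integer(snapshot_every)),
                   class = "simulation_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  rs_name <- if (inherits(cfg$rule_set, "rule_set")) cfg$rule_set$name
             else cfg$rule_set
  chk(rs_name %in% c("PE", "PE-HS", "PE-PP", "OSS-FF", "PE-OXY", "PE-ENDO"),
      paste0("unknown rule set: ", rs_name))
  chk(is.numeric(cfg$horizon) && cfg$horizon >= 0,
      "horizon must be >= 0 days")
  chk(cfg$dt > 0, "dt must be > 0")
  chk(all(unlist(cfg$rates) >= 0), "production rates must be >= 0")
  chk(cfg$transport$C >= 0, "oxygen consumption C must be >= 0")
  chk(cfg$transport$A > 0 && cfg$transport$O > 0,
      "transport diffusion factors must be > 0")
  chk(cfg$transport$O_unit > 0, "O_unit must be > 0")
  chk(cfg$transport$a_oss > 0, "A-OSS gate must be > 0")
  chk(cfg$callus_tendon >= 0 && cfg$callus_tendon <= 1,
      "callus_tendon must be a fraction")
  chk(cfg$tendon_law$zero_strain > cfg$tendon_law$peak_strain,
      "tendon law: zero_strain must exceed peak_strain")
  if (length(problems))
    stop("invalid simulation configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(cfg)
}

#' Load a simulation configuration from a YAML file
#'
#' Missing keys fall back to the defaults of [simulation_config()]; an
#' empty file yields the full default configuration (PE rule set, 2 N,
#' 140 days). All schema violations are reported at once.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `simulation_config` with attribute `"source"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("invalid simulation configuration:\n  unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- do.call(simulation_config, raw)
  attr(cfg, "source") <- normalizePath(path)
  cfg
}

resolve_rule_set <- function(cfg) {
  if (inherits(cfg$rule_set, "rule_set")) return(cfg$rule_set)
  rule_set(cfg$rule_set, endo = cfg$endo)
}

#' Run the iterative healing simulation
#'
#' Daily loop over the configured horizon. Each day: (1) the material state
#' is assembled from current densities and fibrils and the load ramp is
#' solved, yielding the biophysical stimuli; (2) the nodal transport fields
#' advance (cells always; angiogenesis gated by the day's shear strain,
#' vessel maturation, then oxygen with cellular consumption, when the rule
#' set requires oxygen); (3) every callus element is classified to the
#' tissue it produces (plus the endochondral gate for PE-ENDO); (4) tissue
#' is produced and the others degrade; (5) fibrils reorient toward the
#' maximum principal strain; (6) summary rows are recorded. Deterministic
#' for a fixed configuration and seed.
#'
#' @param config A [simulation_config()].
#' @param quiet Suppress the per-day progress line.
#' @return An object of class `healing_history`: list with `table` (one row
#'   per day: mean callus densities as fractions, stiffness at peak load
#'   (N/mm), callus bone volume (mm^3), vascularized-node fraction, mean
#'   oxygen), `mesh`, `state`, `transport`, `stimuli` (final day),
#'   `snapshots` and the resolved `config`.
#' @export
run_healing <- function(config = simulation_config(), quiet = TRUE) {
  validate_config(config)
  rs <- resolve_rule_set(config)
  set.seed(config$seed)

  mesh <- build_mesh(config$geometry)
  ops <- mesh_operators(mesh, config$material$poisson)
  state <- element_state_init(mesh, config$callus_tendon,
                              config$reorientation$n_fibrils)
  callus <- mesh$region == "callus"
  Vc <- mesh$volumes[callus]
  callus_nodes <- which(ops$callus_lumped > 0)

  D_cells <- config$transport$D_cells %||%
    as.numeric(calibrate_cell_infiltration(mesh, dt = config$dt, ops = ops))
  A <- config$transport$A * D_cells
  O <- config$transport$O * config$transport$O_unit
  gate <- angio_gate(config$transport$a_oss, config$transport$maturation)
  needs_oxy <- isTRUE(rs$needs_oxygen)

  nn <- ops$nn
  tr <- list(cells = numeric(nn), angio = numeric(nn),
             oxygen = numeric(nn), vessels = logical(nn))
  # All three fields enter from the external callus surface (extrinsic
  # compartment); the stump cross-sections are no-flux.
  src_cells <- mesh$sets$surface
  src_angio <- mesh$sets$surface
  tr$angio[src_angio] <- 1
  tr$oxygen[src_angio] <- 1
  tr$cells[src_cells] <- 1

  inflam <- c(config$inflammatory, list(rate = config$rates$default))
  ndays <- config$horizon
  rows <- vector("list", ndays + 1L)
  snapshots <- list()

  record <- function(day, sol) {
    dens <- state$densities[callus, , drop = FALSE]
    means <- colSums(dens * Vc) / sum(Vc)
    data.frame(day = day,
               fat = means["fat"], tendon = means["tendon"],
               cartilage = means["cartilage"], bone = means["bone"],
               stiffness = sol$stiffness,
               bone_volume = sum(dens[, "bone"] * Vc),
               vascularized = mean(tr$vessels[callus_nodes]),
               mean_oxygen = if (needs_oxy)
                 callus_mean(mesh, tr$oxygen, ops) else NA_real_,
               row.names = NULL)
  }

  mat <- assemble_material(state, config$material, config$protocol$axis)
  sol <- solve_ramp(mesh, mat, config$protocol, config$material, ops)
  rows[[1L]] <- record(0L, sol)

  for (day in seq_len(ndays)) {
    if (day > 1L) {
      mat <- assemble_material(state, config$material, config$protocol$axis)
      sol <- solve_ramp(mesh, mat, config$protocol, config$material, ops)
    }

    tr$cells <- diffuse_step(mesh, tr$cells, D_cells, config$dt,
                             src_cells, ops)
    if (needs_oxy) {
      tr$angio <- angiogenesis_step(mesh, tr$angio, A, config$dt, sol,
                                    gate, src_angio, ops)
      tr$vessels <- mature_vessels(tr$angio, tr$vessels, gate)
      src_oxy <- sort(unique(c(src_angio, which(tr$vessels))))
      tr$oxygen <- oxygen_step(mesh, tr$oxygen, O, config$transport$C,
                               tr$cells, config$dt, src_oxy, ops)
    }

    cells_e <- node_to_elem(ops, tr$cells)
    stim <- list(e1 = sol$e1, hydro = sol$hydro, pp = sol$pp,
                 oss = sol$oss, ff = sol$ff)
    if (needs_oxy) {
      stim$oxygen <- 100 * node_to_elem(ops, tr$oxygen)
      blood_n <- as.numeric(tr$vessels)
      stim$blood <- as.numeric(Matrix::crossprod(ops$transfer,
                                                 blood_n)) > 0
    }
    tissue <- classify_elements(rs, stim)
    if (rs$name == "PE-ENDO")
      tissue <- endochondral_gate(tissue, sol$e1,
                                  state$densities[, "cartilage"],
                                  state$densities[, "bone"], rs$endo)

    rate <- numeric(ops$ne)
    rate[tissue %in% c("cartilage", "fat")] <- config$rates$default
    rate[tissue == "bone"] <- config$rates$bone
    is_t <- tissue == "tendon"
    if (any(is_t)) {
      rate[is_t] <- if (identical(rs$tendon_law, "strain")) {
        tendon_rate_law(pmax(sol$e1[is_t], 0),
                        peak_rate = config$rates$default,
                        peak_strain = config$tendon_law$peak_strain,
                        zero_strain = config$tendon_law$zero_strain)
      } else config$rates$default
    }

    state <- produce_and_degrade(state, tissue, rate, cells_e,
                                 config$dt, day, inflam)
    if (isTRUE(config$reorientation$enabled))
      state <- reorient_fibrils(state, sol$dir, config$dt,
                                config$reorientation$total_days)
    state$integrals <- state$integrals + state$densities * config$dt

    rows[[day + 1L]] <- record(day, sol)
    if (config$snapshot_every > 0L && day %% config$snapshot_every == 0L)
      snapshots[[as.character(day)]] <-
        list(day = day, densities = state$densities, transport = tr,
             stimuli = sol)
    if (!quiet)
      message(sprintf(
        "day %3d  T %5.1f%%  C %5.1f%%  B %5.1f%%  k %6.2f N/mm", day,
        100 * rows[[day + 1L]]$tendon, 100 * rows[[day + 1L]]$cartilage,
        100 * rows[[day + 1L]]$bone, rows[[day + 1L]]$stiffness))
  }

  structure(list(table = do.call(rbind, rows), mesh = mesh, ops = ops,
                 state = state, transport = tr, stimuli = sol,
                 snapshots = snapshots, D_cells = D_cells,
                 config = config),
            class = "healing_history")
}

#' @export
print.healing_history <- function(x, ...) {
  last <- x$table[nrow(x$table), ]
  cat("<healing_history> ", nrow(x$table) - 1L, " days, rule set ",
      resolve_rule_set(x$config)$name, "\n", sep = "")
  cat(sprintf(paste0("  final: tendon %.1f%%, cartilage %.1f%%, bone",
                     " %.1f%%, stiffness %.2f N/mm, bone volume %.2f mm^3\n"),
              100 * last$tendon, 100 * last$cartilage, 100 * last$bone,
              last$stiffness, last$bone_volume))
  invisible(x)
}

sweep_keys <- c(A = "A", O = "O", C = "C", A_OSS = "a_oss",
                `A-OSS` = "a_oss", a_oss = "a_oss", D_cells = "D_cells",
                maturation = "maturation")

#' One-factor-at-a-time parameter sweep
#'
#' Runs the baseline configuration plus one run per grid value that
#' differs from the baseline, varying a single transport parameter at a
#' time (the sensitivity design: angiogenesis and oxygen diffusivity
#' factors, consumption, and the angiogenesis strain gate). All runs share
#' the baseline seed.
#'
#' @param config Baseline [simulation_config()].
#' @param grid Named list of value vectors; recognized names: `"A"`, `"O"`,
#'   `"C"`, `"A_OSS"` (alias `"A-OSS"`, `"a_oss"`), `"D_cells"`,
#'   `"maturation"`.
#' @param quiet Passed to [run_healing()].
#' @return List with `histories` (named list, first entry `"baseline"`)
#'   and `manifest` (data frame mapping run label to key and value).
#' @export
parameter_sweep <- function(config = simulation_config(), grid,
                            quiet = TRUE) {
  unknown <- setdiff(names(grid), names(sweep_keys))
  if (length(unknown))
    stop("unknown sweep key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  plan <- list()
  for (key in names(grid)) {
    field <- sweep_keys[[key]]
    base_val <- config$transport[[field]]
    for (val in grid[[key]]) {
      if (!is.null(base_val) && isTRUE(all.equal(val, base_val))) next
      plan[[paste0(key, "=", val)]] <- list(field = field, value = val)
    }
  }
  histories <- list(baseline = run_healing(config, quiet = quiet))
  manifest <- data.frame(label = "baseline", key = NA_character_,
                         value = NA_real_, stringsAsFactors = FALSE)
  for (label in names(plan)) {
    cfg <- config
    cfg$transport[[plan[[label]]$field]] <- plan[[label]]$value
    histories[[label]] <- run_healing(cfg, quiet = quiet)
    manifest <- rbind(manifest,
                      data.frame(label = label, key = plan[[label]]$field,
                                 value = plan[[label]]$value,
                                 stringsAsFactors = FALSE))
  }
  list(histories = histories, manifest = manifest)
}
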