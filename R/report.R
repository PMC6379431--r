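# Pipeline orchestration: one structured config describing the structures
# and residue conventions, one machine-readable JSON report containing
# every stage's numbers. Stages are isolated: a failing stage is recorded
# in the report and the independent stages still run.

.REPORT_SCHEMA_VERSION <- "1.0"

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with claudin-3 defaults:
#' vertex residue 134 (the TM3 thenar position), proximal arm 118-133,
#' distal arm 135-149, superposition core = the transmembrane rigid
#' segments 1-27, 78-133, 160-200 (the distal TM3 arm is excluded so the
#' hinged part cannot bias the core fit), TM ranges and topology from
#' [claudin_tm_defaults()], pocket rims 146-147 (upper) / 158-159
#' (lower), extracellular displacement range 28-77.
#'
#' @param structures named character vector of coordinate file paths
#'   (names are the labels used in the report).
#' @param chains chain ids of the molecule copies to analyse.
#' @param vertex_residue TM3 vertex (thenar) residue number.
#' @param proximal_range,distal_range bend-angle arm intervals.
#' @param core_residues initial superposition core residue numbers.
#' @param reject_threshold,adaptive core rejection setting.
#' @param tm_ranges,topology membrane-frame inputs.
#' @param upper_residues,lower_residues pocket rims.
#' @param ecd_range displacement-profile interval.
#' @param bfactor_scope "backbone" or "all".
#' @param binding_csv optional binding CSV path.
#' @param seed integer seed recorded in the report.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(structures,
                            chains = c("A", "C"),
                            vertex_residue = 134,
                            proximal_range = c(118, 133),
                            distal_range = c(135, 149),
                            core_residues = c(1:27, 78:133, 160:200),
                            reject_threshold = 2.0,
                            adaptive = FALSE,
                            tm_ranges = claudin_tm_defaults()$tm_ranges,
                            topology = claudin_tm_defaults()$topology,
                            upper_residues = c(146, 147),
                            lower_residues = c(158, 159),
                            ecd_range = c(28, 77),
                            bfactor_scope = "backbone",
                            binding_csv = NULL,
                            seed = 1) {
  if (is.null(names(structures)) || any(names(structures) == ""))
    stop("structures must be a named vector (label = path)")
  structure(as.list(environment()), class = "analysis_config")
}

# run one stage, capturing errors into the report
.stage <- function(expr) {
  tryCatch(list(ok = TRUE, value = expr),
           error = function(e) list(ok = FALSE, error = conditionMessage(e)))
}

#' Run the full structure-comparison report
#'
#' Loads every configured structure and computes, per structure: per-chain
#' and mean TM3 bend angles, the membrane frame, the pocket aperture per
#' chain, and the cross-chain B-factor comparison; per unordered pair of
#' structures: the low-RMSD-core superposition, the extracellular
#' displacement profile with its maximum shift, the bend-angle
#' difference, and the pocket-width difference. An optional binding CSV
#' adds a one-site fit. Failing stages are recorded as errors without
#' aborting the rest; `status` is "ok" or "partial".
#'
#' @param config an [analysis_config()].
#' @return a nested list (class `analysis_report`) serializable with
#'   [write_report()].
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  report <- list(schema_version = .REPORT_SCHEMA_VERSION,
                 package_version = as.character(utils::packageVersion("cldngeom")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 config = .serialize_config(config),
                 structures = list(), pairs = list(), errors = list())
  models <- list()
  for (lab in names(config$structures)) {
    st <- .stage(read_structure(config$structures[[lab]]))
    if (!st$ok) {
      report$errors[[paste0("load_", lab)]] <- st$error
      next
    }
    models[[lab]] <- st$value
    report$structures[[lab]] <- .structure_section(st$value, config)
  }
  labs <- names(models)
  if (length(labs) >= 2) {
    for (i in seq_len(length(labs) - 1)) for (j in (i + 1):length(labs)) {
      key <- paste(labs[i], labs[j], sep = "_vs_")
      report$pairs[[key]] <-
        .pair_section(models[[labs[i]]], models[[labs[j]]],
                      report$structures[[labs[i]]],
                      report$structures[[labs[j]]], config)
    }
  }
  if (!is.null(config$binding_csv)) {
    bs <- .stage({
      series <- read_binding_csv(config$binding_csv)
      fit <- fit_one_site(series)
      list(kd_uM = fit$kd, rss = fit$rss, converged = fit$converged,
           n_points = length(series$ligand_concentrations))
    })
    if (bs$ok) report$binding <- bs$value
    else report$errors$binding <- bs$error
  }
  report$status <- if (length(report$errors) == 0 &&
                       !.any_stage_error(report)) "ok" else "partial"
  structure(report, class = "analysis_report")
}

.any_stage_error <- function(report) {
  has_err <- function(x) {
    if (is.list(x))
      any(names(x) == "error") || any(vapply(x, has_err, logical(1)))
    else FALSE
  }
  has_err(report$structures) || has_err(report$pairs)
}

.structure_section <- function(model, cfg) {
  out <- list(identifier = model$identifier,
              n_atoms = nrow(model$atoms),
              chains = sort(unique(model$atoms$chain)))
  bend <- .stage({
    mb <- mean_bend(model, cfg$chains, cfg$proximal_range,
                    cfg$vertex_residue, cfg$distal_range)
    list(mean_angle_deg = mb$mean_angle,
         per_chain_deg = as.list(mb$per_chain),
         failed_chains = as.list(mb$failed))
  })
  out$bend <- if (bend$ok) bend$value else list(error = bend$error)
  pocket <- .stage({
    widths <- lapply(cfg$chains, function(ch) {
      frame <- estimate_membrane_normal(model, cfg$tm_ranges, chain = ch,
                                        topology = cfg$topology)
      pa <- pocket_vertical_width(model, frame, cfg$upper_residues,
                                  cfg$lower_residues, chain = ch)
      list(chain = ch, vertical_width_A = pa$vertical_width,
           upper_projection_A = pa$upper_projection,
           lower_projection_A = pa$lower_projection,
           membrane_normal = as.numeric(frame$normal))
    })
    names(widths) <- cfg$chains
    widths
  })
  out$pocket <- if (pocket$ok) pocket$value else list(error = pocket$error)
  if (length(cfg$chains) >= 2) {
    bf <- .stage({
      cmp <- compare_chains(model, cfg$chains[1], cfg$chains[2],
                            atom_scope = cfg$bfactor_scope)
      list(chain_a = cmp$chain_a, chain_b = cmp$chain_b,
           mean_delta_A2 = cmp$mean_delta,
           fraction_b_higher = cmp$fraction_b_higher,
           n_shared = cmp$n_shared)
    })
    out$bfactor <- if (bf$ok) bf$value else list(error = bf$error)
  }
  out
}

.pair_section <- function(model_a, model_b, sec_a, sec_b, cfg) {
  out <- list()
  sup <- .stage({
    chain_map <- stats::setNames(cfg$chains[1], cfg$chains[1])
    res <- core_superpose(model_a, model_b, chain_map,
                          initial_core = cfg$core_residues,
                          reject_threshold = cfg$reject_threshold,
                          adaptive = cfg$adaptive)
    prof <- displacement_profile(model_a, model_b, res,
                                 residues = seq(min(cfg$ecd_range),
                                                max(cfg$ecd_range)))
    list(core_size = nrow(res$core_residues),
         core_rmsd_A = res$core_rmsd,
         iterations = res$iterations,
         n_rejected = nrow(res$rejected_residues),
         rotation = res$transform$rotation,
         translation = res$transform$translation,
         ecd_profile = list(
           resno = prof$profile$resno,
           displacement_A = prof$profile$displacement),
         max_ecd_shift_A = prof$max_shift$shift,
         max_ecd_shift_residue = prof$max_shift$resno)
  })
  out$superposition <- if (sup$ok) sup$value else list(error = sup$error)
  ang_a <- sec_a$bend$mean_angle_deg; ang_b <- sec_b$bend$mean_angle_deg
  if (!is.null(ang_a) && !is.null(ang_b))
    out$bend_difference_deg <- bend_difference(ang_a, ang_b)
  w_a <- sec_a$pocket[[cfg$chains[1]]]$vertical_width_A
  w_b <- sec_b$pocket[[cfg$chains[1]]]$vertical_width_A
  if (!is.null(w_a) && !is.null(w_b)) {
    out$pocket_width_difference_A <- w_a - w_b
    out$pocket_narrower_in <- if (w_a < w_b) "first" else "second"
  }
  out
}

.serialize_config <- function(cfg) {
  s <- unclass(cfg)
  s$structures <- as.list(s$structures)
  s
}

#' Write a report as JSON
#'
#' @param report a [run_report()] result (or any list).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write synthetic fixtures with a ground-truth sidecar
#'
#' Generates coordinate/CSV fixtures of the requested kind under
#' `out_dir` together with a `truth.json` recording the generator
#' parameters. Deterministic given the seed (byte-identical reruns).
#'
#' Kinds: "kinked_pair" (two claudin-like models with kink angles
#' `theta_a`/`theta_b`, defaults 25 and 17), "domain_pair" (core plus
#' mobile domain displaced by `shift` Angstrom, default 5), "bundle" (a
#' four-helix bundle with known mean axis), "binding" (a one-site
#' titration CSV with known Kd, default 0.05 uM).
#'
#' @param kind fixture kind, see above.
#' @param parameters named list overriding kind-specific defaults.
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @return named list of written file paths, invisibly.
#' @export
make_fixtures <- function(kind = c("kinked_pair", "domain_pair", "bundle",
                                   "binding"),
                          parameters = list(), seed = 1, out_dir = ".") {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name, default) {
    if (!is.null(parameters[[name]])) parameters[[name]] else default
  }
  files <- list()
  truth <- list(kind = kind, seed = seed)
  if (kind == "kinked_pair") {
    th_a <- p("theta_a", 25); th_b <- p("theta_b", 17)
    ma <- make_claudin_like(th_a, seed = seed)
    mb <- make_claudin_like(th_b, seed = seed)
    files$a <- file.path(out_dir, "kinked_a.pdb")
    files$b <- file.path(out_dir, "kinked_b.pdb")
    write_pdb(ma, files$a); write_pdb(mb, files$b)
    truth$kink_angle_a <- th_a; truth$kink_angle_b <- th_b
    truth$vertex_residue <- 134
  } else if (kind == "domain_pair") {
    shift <- p("shift", 5); noise_sd <- p("noise_sd", 0)
    core <- make_ideal_helix(helix_spec(p("n_core", 30)), resno_start = 1)
    mobile <- make_ideal_helix(
      helix_spec(p("n_mobile", 20), origin = c(10, 0, 0)), resno_start = 101)
    pair <- make_domain_pair(core, mobile,
                             translation = c(shift, 0, 0),
                             noise_sd = noise_sd, seed = seed)
    files$a <- file.path(out_dir, "domain_a.pdb")
    files$b <- file.path(out_dir, "domain_b.pdb")
    write_pdb(pair$a, files$a); write_pdb(pair$b, files$b)
    truth$shift_A <- shift; truth$noise_sd <- noise_sd
    truth$core_residues <- 1:p("n_core", 30)
    truth$mobile_residues <- 101:(100 + p("n_mobile", 20))
  } else if (kind == "bundle") {
    tilts <- p("tilt_angles", c(10, -10, 10, -10))
    m <- make_helix_bundle(p("n_helices", 4), tilts, p("spacing", 10))
    files$bundle <- file.path(out_dir, "bundle.pdb")
    write_pdb(m, files$bundle)
    truth$tilt_angles <- tilts
    truth$true_normal <- as.numeric(attr(m, "true_normal"))
  } else if (kind == "binding") {
    kd <- p("kd", 0.05); noise_sd <- p("noise_sd", 0.02)
    series <- simulate_binding(kd, noise_sd = noise_sd, seed = seed)
    height <- p("total_height", 100)
    d <- data.frame(concentration_uM = series$ligand_concentrations,
                    bound_height = round(series$fraction_bound * height, 4),
                    unbound_height = round((1 - series$fraction_bound) * height, 4))
    files$csv <- file.path(out_dir, "binding.csv")
    utils::write.csv(d, files$csv, row.names = FALSE)
    truth$kd_uM <- kd; truth$noise_sd <- noise_sd
  }
  files$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(files)
}
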