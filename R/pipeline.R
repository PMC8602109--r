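# Config-driven orchestration of the comparative design: systems x states
# x replicas of synthetic ensembles, pushed through every analysis stage in
# dependency order, with a machine-readable run manifest. All stage outputs
# are pure functions of (config, seed).

#' Load and validate a study configuration
#'
#' Configurations are plain JSON. See
#' `system.file("extdata", "demo_config.json", package = "trajan")` for the
#' bundled demo: a two-system x three-state x two-replica synthetic study.
#' Recognized top-level fields and their defaults are documented in the
#' demo file; stage parameters default to the conventional values
#' (contact cutoff 5 Angstrom, perturbation threshold 5, sieve 10).
#'
#' @param path JSON file, or a list already parsed.
#' @return validated config list (class `StudyConfig`).
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(
    n_residues = 14L, atoms_per_residue = 3L, n_frames = 240L,
    frame_stride = 1, n_replicas = 2L,
    systems = c("sysA", "sysB"),
    states = c("apo", "holo", "holo+ATP"),
    mode_lambda = c(1.0, 0.25), noise_sigma = 0.15,
    state_scale = c(apo = 1.0, holo = 0.85, `holo+ATP` = 0.55),
    displaced_block = NULL, displacement = c(0, 3.5, 0),
    window = list(last_frames = 120L),
    contact_cutoff = 5.0, dpn_threshold = 5.0, sieve = 10L, k = 4L,
    ed_modes = 4L, rmsip_modes = 3L,
    wisp = list(source = 2L, sink = NULL, delta = 1.0),
    site = list(residues = NULL, cutoff = NULL),
    seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$displaced_block))
    cfg$displaced_block <- seq.int(max(2L, cfg$n_residues - 3L),
                                   cfg$n_residues - 1L)
  if (is.null(cfg$wisp$sink)) cfg$wisp$sink <- cfg$n_residues - 1L
  if (is.null(cfg$wisp$delta)) cfg$wisp$delta <- 1.0
  if (is.null(cfg$site$residues))
    cfg$site$residues <- cfg$displaced_block
  stopifnot(cfg$n_residues >= 6L, cfg$n_frames >= cfg$k * cfg$sieve,
            cfg$contact_cutoff > 0, cfg$dpn_threshold >= 0,
            cfg$sieve >= 1L, cfg$k >= 1L,
            all(cfg$displaced_block >= 1L),
            all(cfg$displaced_block <= cfg$n_residues))
  if (length(cfg$displaced_block) >= cfg$n_residues)
    stop("displaced_block must be a strict subset of residues")
  class(cfg) <- c("StudyConfig", "list")
  cfg
}

.window_of <- function(cfg) {
  w <- cfg$window
  if (is.list(w) && !is.null(w$last_frames)) last_frames(w$last_frames)
  else if (is.list(w) && !is.null(w$last_ns)) last_ns(w$last_ns)
  else unlist(w)
}

# deterministic per-ensemble seed; kept well below 2^31
.subseed <- function(seed, sys_i, state_i, rep) {
  (as.integer(seed) %% 100000L) * 10000L +
    sys_i * 1000L + state_i * 100L + rep
}

#' Generate the synthetic ensembles a config describes
#'
#' Each system gets a miniature two-chain structure with two planted
#' orthonormal modes (a bending-like profile and a counter-phase profile);
#' states share the modes but differ in amplitude (`state_scale`: ligand
#' binding stiffens the ensemble) and the non-apo states carry a rigid
#' displacement of a residue block (the contact rearrangement an apo-vs-
#' holo perturbation network should detect).
#'
#' @param cfg a `StudyConfig`.
#' @param seed integer; overrides `cfg$seed` when given.
#' @return nested list `ensembles[[system]][[state]][[replica]]` plus
#'   `structure` and `specs` attributes.
#' @export
simulate_study <- function(cfg, seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed
  st <- synthetic_structure(cfg$n_residues, cfg$atoms_per_residue)
  nres <- cfg$n_residues
  prof1 <- sin(seq(0, pi, length.out = nres))
  prof2 <- cos(seq(0, 2 * pi, length.out = nres))
  modes <- orthonormalize_modes(project_out_rigid_body(
    cbind(plant_mode(st, prof1, c(1, 0, 0)),
          plant_mode(st, prof2, c(0, 0, 1))),
    st$reference_coords))
  out <- list(); specs <- list()
  for (si in seq_along(cfg$systems)) {
    sys <- cfg$systems[[si]]
    out[[sys]] <- list()
    for (ki in seq_along(cfg$states)) {
      state <- cfg$states[[ki]]
      scale <- cfg$state_scale[[state]]
      if (is.null(scale)) scale <- 1.0
      # system B is globally a bit more flexible, mirroring a softer isoform
      sys_scale <- if (si == 1L) 1.0 else 1.25
      stx <- st
      if (state != "apo")
        stx$reference_coords <- .displace_block(
          st, st$reference_coords, cfg$displaced_block,
          unlist(cfg$displacement))
      spec <- gaussian_ensemble_spec(
        stx, modes = modes,
        lambdas = sort(cfg$mode_lambda * scale * sys_scale,
                       decreasing = TRUE),
        noise_sigma = cfg$noise_sigma)
      specs[[paste(sys, state)]] <- spec
      out[[sys]][[state]] <- lapply(seq_len(cfg$n_replicas), function(r)
        make_gaussian_ensemble(spec, cfg$n_frames,
                               seed = .subseed(seed, si, ki, r),
                               frame_stride = cfg$frame_stride,
                               replica_id = r, state_label = state))
    }
  }
  attr(out, "structure") <- st
  attr(out, "specs") <- specs
  out
}

.num <- function(x, digits = 6) round(as.numeric(x), digits)

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- superposition, RMSD/RMSF,
#' essential dynamics (+ cross-replica RMSIP), DCC (+ Tanimoto between
#' states), contact/perturbation networks, communication paths, clustering,
#' site analysis -- over the synthetic study a config describes, and writes
#' a collated report directory plus a run manifest. Reruns with the same
#' `(config, seed)` are byte-identical.
#'
#' @param config path to a JSON config, or a parsed list.
#' @param out_dir output directory (created).
#' @param seed overrides the config seed when given.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (inherits(config, "StudyConfig")) config else load_config(config)
  if (is.null(seed)) seed <- cfg$seed
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  win <- .window_of(cfg)
  ens <- simulate_study(cfg, seed)
  st <- attr(ens, "structure")
  bb <- select_atoms(st, "backbone")
  files <- character(0)
  emit <- function(name) { files <<- c(files, name); file.path(out_dir, name) }

  # --- reference: plain coordinate average of the bound state's window
  refs <- lapply(ens, function(sys_states) {
    bound <- sys_states[[length(sys_states)]][[1]]
    average_structure(bound, window = win, selection = bb)
  })

  # --- RMSD table (replica mean +/- SD against the bound-state average)
  rows <- list()
  for (sys in names(ens)) for (state in names(ens[[sys]])) {
    means <- c(); sds <- c()
    for (x in ens[[sys]][[state]]) {
      rs <- rmsd_series(x, reference = refs[[sys]], selection = bb,
                        window = win)
      means <- c(means, rs$mean); sds <- c(sds, rs$sd)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      system = sys, state = state,
      t(setNames(.num(means), paste0("rep", seq_along(means)))),
      t(setNames(.num(sds), paste0("rep", seq_along(sds), "_sd"))),
      average = .num(mean(means)))
  }
  write.csv(do.call(rbind, rows), emit("rmsd_table.csv"), row.names = FALSE)

  # --- RMSF profiles
  rows <- list()
  for (sys in names(ens)) for (state in names(ens[[sys]])) {
    pr <- rmsf_profile(ens[[sys]][[state]], selection = bb, window = win)
    rows[[length(rows) + 1L]] <- data.frame(
      system = sys, state = state, res_index = pr$res_index,
      rmsf_mean = .num(pr$mean), rmsf_sd = .num(pr$sd))
  }
  write.csv(do.call(rbind, rows), emit("rmsf_profile.csv"), row.names = FALSE)

  # --- essential dynamics + RMSIP between replicas
  ed_rows <- list(); sim_rows <- list()
  for (sys in names(ens)) for (state in names(ens[[sys]])) {
    eds <- lapply(ens[[sys]][[state]], compute_ed,
                  selection = bb, window = win)
    vf <- variance_fractions(eds[[1]], cfg$ed_modes)
    ed_rows[[length(ed_rows) + 1L]] <- data.frame(
      system = sys, state = state,
      t(setNames(round(vf$fractions, 1),
                 paste0("proj", seq_len(cfg$ed_modes)))),
      total = round(vf$total, 1))
    if (length(eds) > 1L)
      for (a in seq_len(length(eds) - 1L)) for (b in seq.int(a + 1L, length(eds)))
        sim_rows[[length(sim_rows) + 1L]] <- data.frame(
          system = sys, state = state, replica_a = a, replica_b = b,
          rmsip = .num(mode_similarity(eds[[a]], eds[[b]],
                                       cfg$rmsip_modes)$rmsip))
  }
  write.csv(do.call(rbind, ed_rows), emit("ed_variance_table.csv"),
            row.names = FALSE)
  if (length(sim_rows))
    write.csv(do.call(rbind, sim_rows), emit("ed_similarity.csv"),
              row.names = FALSE)

  # --- DCC per state (replica 1) and Tanimoto between states
  dccs <- list()
  for (sys in names(ens)) for (state in names(ens[[sys]])) {
    d <- compute_dcc(ens[[sys]][[state]][[1]], window = win)
    dccs[[paste(sys, state)]] <- d
    write_dcc_csv(d, emit(sprintf("dcc_%s_%s.csv", sys, gsub("[+]", "", state))))
  }
  tan <- list()
  for (sys in names(ens)) {
    sts <- names(ens[[sys]])
    for (a in seq_len(length(sts) - 1L)) for (b in seq.int(a + 1L, length(sts)))
      tan[[length(tan) + 1L]] <- data.frame(
        system = sys, state_a = sts[a], state_b = sts[b],
        tanimoto = .num(tanimoto_similarity(dccs[[paste(sys, sts[a])]],
                                            dccs[[paste(sys, sts[b])]])))
  }
  write.csv(do.call(rbind, tan), emit("dcc_tanimoto.csv"), row.names = FALSE)

  # --- perturbation network apo vs holo (replica-averaged)
  for (sys in names(ens)) {
    if (!all(c("apo", "holo") %in% names(ens[[sys]]))) next
    na <- dynamical_contact_network(ens[[sys]][["apo"]],
                                    cutoff = cfg$contact_cutoff, window = win)
    nb <- dynamical_contact_network(ens[[sys]][["holo"]],
                                    cutoff = cfg$contact_cutoff, window = win)
    pn <- perturbation(na, nb, threshold = cfg$dpn_threshold)
    write_edges_csv(pn, emit(sprintf("dpn_%s_apo_holo.csv", sys)))
    if (nrow(pn$edges))
      write_graphml(pn, emit(sprintf("dpn_%s_apo_holo.graphml", sys)), st)
  }

  # --- communication paths on the holo state; the mask keeps sequence
  # neighbours (exclude_adjacent = 0) since paths may run along the chain
  for (sys in names(ens)) {
    state <- if ("holo" %in% names(ens[[sys]])) "holo" else names(ens[[sys]])[1]
    mask <- dynamical_contact_network(ens[[sys]][[state]],
                                      cutoff = cfg$contact_cutoff, window = win,
                                      exclude_adjacent = 0L)
    g <- build_graph(dccs[[paste(sys, state)]], st, mask = mask,
                     mask_min_weight = 1)
    op <- optimal_path(g, cfg$wisp$source, cfg$wisp$sink)
    if (op$found) {
      ps <- suboptimal_paths(g, cfg$wisp$source, cfg$wisp$sink,
                             mode = "within_delta",
                             k_or_delta = cfg$wisp$delta)
      write_path_report(ps, st,
                        tsv = emit(sprintf("paths_%s.tsv", sys)),
                        json = emit(sprintf("paths_%s.json", sys)))
    }
  }

  # --- clustering of the holo ensemble (replica 1)
  for (sys in names(ens)) {
    state <- if ("holo" %in% names(ens[[sys]])) "holo" else names(ens[[sys]])[1]
    x <- ens[[sys]][[state]][[1]]
    cl <- kmeans_rmsd(x, selection = bb, k = cfg$k, sieve = cfg$sieve,
                      seed = seed, window = win)
    write_cluster_report(cl, x,
                         csv = emit(sprintf("clusters_%s.csv", sys)),
                         json = emit(sprintf("clusters_%s.json", sys)))
  }

  # --- site pre-organization vs the bound-state reference
  site_sel <- select_atoms(st, "heavy", res_index = cfg$site$residues)
  rows <- list()
  for (sys in names(ens)) for (state in names(ens[[sys]])) {
    sd_ <- site_rmsd_distribution(ens[[sys]][[state]][[1]], refs[[sys]],
                                  site_selection = site_sel,
                                  fit_selection = bb, window = win)
    cut <- cfg$site$cutoff
    ov <- if (!is.null(cut)) overlap_fraction(sd_, cut)
          else if (length(sd_$peaks) >= 2L) overlap_fraction(sd_)
          else list(fraction = NA_real_, cutoff = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      system = sys, state = state, mean_rmsd = .num(mean(sd_$values)),
      peaks = paste(sprintf("%.2f", sd_$peaks), collapse = ";"),
      overlap_fraction = .num(ov$fraction), cutoff = .num(ov$cutoff))
  }
  write.csv(do.call(rbind, rows), emit("site_preorganization.csv"),
            row.names = FALSE)

  # --- manifest
  manifest <- list(
    package = "trajan",
    version = as.character(utils::packageVersion("trajan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    parameters = cfg[setdiff(names(cfg), c("systems", "states"))],
    systems = cfg$systems, states = cfg$states,
    files = sort(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}
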