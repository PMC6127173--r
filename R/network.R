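## reaction_network: declarative three-compartment VEGF network ------------
##
## A model is a plain list of data frames (compartments, species,
## reactions, transports) plus the set of complexes counted as the
## pro-angiogenic signal. Reactions are reversible bimolecular bindings
## A + B <-> C with mass-action rates. Transports are linear amount
## fluxes (conductances); secretion and clearance are transports with a
## missing source / destination.

#' Construct a VEGF compartment model
#'
#' Low-level constructor used both by [build_default_network()] and by
#' tests that assemble minimal networks (e.g. a single binding pair).
#'
#' @param compartments data.frame with columns `name`
#'   (`normal`/`blood`/`tumour`) and `fluid_volume` (cm^3; `NA` for the
#'   tumour, whose interstitial fluid volume is a configurable fraction
#'   of the dynamic total tumour volume).
#' @param species data.frame with columns `name`, `compartment`, `kind`
#'   (`ligand`, `surface_receptor`, `soluble_receptor`, `inhibitor`,
#'   `drug`, `complex`) and `initial` (mol/cm^3).
#' @param reactions data.frame with columns `a`, `b`, `c` (species
#'   names; the complex `c` is formed from `a` + `b`), `kf`
#'   (cm^3 mol^-1 day^-1) and `kr` (day^-1).
#' @param transports data.frame with columns `species`, `from`, `to`
#'   (compartment names; `to = NA` for clearance, `from = NA` for
#'   secretion), `mechanism` (`permeability`, `lymph_flow`, `clearance`,
#'   `secretion`), `rate` (cm^3/day conductance, or mol/day for
#'   secretion) and `vscale` (logical: rate scales with total tumour
#'   volume).
#' @param signal_complexes character vector of complex species (tumour
#'   compartment) whose summed concentration is the angiogenic signal.
#' @param params named list of the parameter table the model was built
#'   from (kept for provenance).
#' @param interstitial_fraction tumour interstitial fluid volume as a
#'   fraction of total tumour volume (the pluggable volume coupling;
#'   default 0.5).
#' @return An object of class `vegf_model`.
#' @export
vegf_model <- function(compartments, species, reactions, transports,
                       signal_complexes = character(0), params = list(),
                       interstitial_fraction = 0.5) {
  model <- structure(
    list(compartments = compartments, species = species,
         reactions = reactions, transports = transports,
         signal_complexes = signal_complexes, params = params,
         interstitial_fraction = interstitial_fraction),
    class = "vegf_model")
  validate_model(model)
}

#' Validate a VEGF compartment model
#'
#' Checks referential integrity (every reaction and transport references
#' declared species), nonnegativity of rates and initial concentrations,
#' uniqueness of names, and that all signal complexes live in the tumour
#' compartment. Returns the model invisibly-validated; signals a classed
#' schema error otherwise.
#'
#' @param model a `vegf_model`.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  cp <- model$compartments
  sp <- model$species
  if (anyDuplicated(cp$name))
    .schema_error("duplicate compartment names")
  if (anyDuplicated(sp$name))
    .schema_error("duplicate species names")
  if (!all(sp$compartment %in% cp$name))
    .schema_error("species declared in unknown compartment: %s",
                  paste(setdiff(sp$compartment, cp$name), collapse = ", "))
  fixed <- cp$fluid_volume[!is.na(cp$fluid_volume)]
  if (any(fixed <= 0))
    .schema_error("compartment fluid volumes must be positive")
  if (model$interstitial_fraction <= 0)
    .schema_error("interstitial fraction must be positive")
  if (any(sp$initial < 0))
    .schema_error("negative initial concentration for species: %s",
                  paste(sp$name[sp$initial < 0], collapse = ", "))
  rx <- model$reactions
  if (nrow(rx)) {
    refs <- unique(c(rx$a, rx$b, rx$c))
    bad <- setdiff(refs, sp$name)
    if (length(bad))
      .schema_error("reaction references undeclared species: %s",
                    paste(bad, collapse = ", "))
    if (any(rx$kf < 0) || any(rx$kr < 0))
      .schema_error("reaction rates must be nonnegative")
  }
  tr <- model$transports
  if (nrow(tr)) {
    bad <- setdiff(unique(tr$species), sp$name)
    if (length(bad))
      .schema_error("transport references undeclared species: %s",
                    paste(bad, collapse = ", "))
    if (any(tr$rate < 0))
      .schema_error("transport rates must be nonnegative")
    if (any(tr$mechanism == "clearance" & !is.na(tr$to)))
      .schema_error("clearance must not have a destination compartment")
    if (any(tr$mechanism == "secretion" & !is.na(tr$from)))
      .schema_error("secretion must not have a source compartment")
  }
  if (length(model$signal_complexes)) {
    bad <- setdiff(model$signal_complexes, sp$name)
    if (length(bad))
      .schema_error("signal complex not declared: %s",
                    paste(bad, collapse = ", "))
    comp <- sp$compartment[match(model$signal_complexes, sp$name)]
    if (any(comp != "tumour"))
      .schema_error("signal complexes must live in the tumour compartment")
  }
  invisible(model)
}

#' Default parameter table for the packaged VEGF network
#'
#' Rate constants, volumes, receptor densities and secretion rates with
#' literature-plausible magnitudes. These values are a synthetic
#' stand-in parameterization: they are chosen for realistic orders of
#' magnitude (picomolar VEGF, 10-300 pM receptor affinities, an
#' antibody with slow plasma clearance), not taken from any fitted
#' animal dataset. All analyses are configuration-driven and accept a
#' modified table.
#'
#' Units: volumes cm^3; association constants `kon_*` cm^3 mol^-1
#' day^-1; dissociation constants `koff_*` day^-1; receptor densities
#' `rho_*` mol per cm^3 of compartment fluid; permeability/lymph
#' conductances cm^3/day (per cm^3 of tumour for `*_t`); clearances
#' 1/day acting on blood concentration; secretion rates mol/day
#' (per cm^3 tumour for `q_*_t` entries).
#'
#' @return named list of parameters.
#' @export
default_network_config <- function() {
  list(
    ## geometry
    vol_normal = 3.0, vol_blood = 1.0, interstitial_fraction = 0.5,
    v0 = 0.004,
    ## binding kinetics
    kon_R1 = 3e14, koff_R1 = 10,
    kon_R2 = 1e14, koff_R2 = 30,
    kon_N = 3e13, koff_N = 100,
    kon_c = 1e14, koff_c = 10,      # coupling of VEGF.R2 with NRP1
    kon_sR1 = 3e14, koff_sR1 = 10,
    kon_a2m = 1e12, koff_a2m = 10,
    kon_bev = 5e14, koff_bev = 8.6, # humanized anti-human-VEGF antibody
    ## receptor surface densities (luminal/abluminal pools)
    rho_R1 = 1e-13, rho_R2 = 1e-13, rho_N1 = 5e-13, rho_N2 = 5e-13,
    rho_tumour_mult = 2,
    ## transport
    ps_normal = 2.0, ps_tumour = 3.0,
    lymph_normal = 1.0, lymph_tumour = 0.2,
    clear_vegf = 20, clear_sR1 = 2, clear_bev = 0.08, clear_cplx = 2,
    ## secretion (tumour cells: human isoforms; endothelium/muscle:
    ## mouse isoforms)
    q_hv121_t = 3e-16, q_hv165_t = 7.5e-16,
    q_mv120_t = 1.4e-16, q_mv164_t = 3.3e-16,
    q_mv120_n = 2e-15, q_mv164_n = 4e-15,
    q_mv164_b = 1.4e-16,
    q_sR1_n = 3e-15, q_sR1_t = 1e-15,
    ## plasma protease inhibitor
    a2m_blood = 1e-11,
    ## growth defaults; ang0 is the equilibrated basal signal of this
    ## parameterization (recomputable via basal_angiogenic_signal())
    psi = 20,
    ang0 = 5.628e-15
  )
}

.param <- function(config, name) {
  if (is.null(config[[name]]) || is.na(suppressWarnings(config[[name]])) &&
      name != "ang0")
    .config_error("missing parameter '%s' in network configuration", name)
  config[[name]]
}

#' Build the default three-compartment VEGF network
#'
#' Assembles the full species roster (human VEGF121/VEGF165 and mouse
#' VEGF120/VEGF164 isoforms; VEGFR1, VEGFR2 and soluble VEGFR1;
#' neuropilin co-receptors NRP1/NRP2; alpha-2-macroglobulin;
#' bevacizumab), with separate luminal and abluminal receptor pools at
#' each blood-tissue interface, reversible mass-action binding,
#' transendothelial permeability and lymphatic transport for the
#' diffusible species (VEGF isoforms, sVEGFR1 and the drug), plasma
#' clearance, and secretion sources (tumour cells secrete the human
#' isoforms; endothelial cells and muscle fibres the mouse isoforms).
#' Bevacizumab binds the human isoforms only. The pro-angiogenic signal
#' is the summed concentration of VEGF-bound VEGFR1/VEGFR2 complexes
#' (with or without neuropilin) on the tumour abluminal endothelium;
#' soluble-VEGFR1 sequestration complexes are excluded.
#'
#' @param config parameter table, see [default_network_config()].
#' @return a validated `vegf_model`.
#' @export
build_default_network <- function(config = default_network_config()) {
  p <- function(name) .param(config, name)

  compartments <- data.frame(
    name = c("normal", "blood", "tumour"),
    fluid_volume = c(p("vol_normal"), p("vol_blood"), NA_real_),
    stringsAsFactors = FALSE)

  surfaces <- data.frame(
    tag = c("nab", "nlu", "tlu", "tab"),
    comp = c("normal", "blood", "blood", "tumour"),
    tum = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)

  isoforms <- data.frame(
    name = c("hv121", "hv165", "mv120", "mv164"),
    human = c(TRUE, TRUE, FALSE, FALSE),
    heparin = c(FALSE, TRUE, FALSE, TRUE),  # NRP-binding isoforms
    stringsAsFactors = FALSE)

  sp <- list(); rx <- list(); tr <- list()
  add_sp <- function(name, comp, kind, initial = 0)
    sp[[length(sp) + 1]] <<- data.frame(
      name = name, compartment = comp, kind = kind, initial = initial,
      stringsAsFactors = FALSE)
  add_rx <- function(a, b, c, kf, kr)
    rx[[length(rx) + 1]] <<- data.frame(
      a = a, b = b, c = c, kf = kf, kr = kr, stringsAsFactors = FALSE)
  add_tr <- function(species, from, to, mechanism, rate, vscale = FALSE)
    tr[[length(tr) + 1]] <<- data.frame(
      species = species, from = from, to = to, mechanism = mechanism,
      rate = rate, vscale = vscale, stringsAsFactors = FALSE)

  ## soluble species in every compartment
  for (co in compartments$name) {
    for (v in isoforms$name) add_sp(paste0(v, "_", .ctag(co)), co, "ligand")
    add_sp(paste0("sR1_", .ctag(co)), co, "soluble_receptor")
    add_sp(paste0("bev_", .ctag(co)), co, "drug")
  }
  add_sp("a2m_b", "blood", "inhibitor", p("a2m_blood"))

  ## receptor pools per surface
  mult <- function(tag) if (tag == "tab") p("rho_tumour_mult") else 1
  for (i in seq_len(nrow(surfaces))) {
    s <- surfaces[i, ]
    add_sp(paste0("R1_", s$tag), s$comp, "surface_receptor",
           p("rho_R1") * mult(s$tag))
    add_sp(paste0("R2_", s$tag), s$comp, "surface_receptor",
           p("rho_R2") * mult(s$tag))
    add_sp(paste0("N1_", s$tag), s$comp, "surface_receptor",
           p("rho_N1") * mult(s$tag))
    add_sp(paste0("N2_", s$tag), s$comp, "surface_receptor",
           p("rho_N2") * mult(s$tag))
  }

  ## surface binding
  for (i in seq_len(nrow(surfaces))) {
    s <- surfaces[i, ]
    ct <- .ctag(s$comp)
    for (j in seq_len(nrow(isoforms))) {
      v <- isoforms[j, ]
      lig <- paste0(v$name, "_", ct)
      for (r in c("R1", "R2")) {
        cx <- paste0(v$name, "_", r, "_", s$tag)
        add_sp(cx, s$comp, "complex")
        add_rx(lig, paste0(r, "_", s$tag), cx,
               p(paste0("kon_", r)), p(paste0("koff_", r)))
      }
      if (v$heparin) {
        for (r in c("N1", "N2")) {
          cx <- paste0(v$name, "_", r, "_", s$tag)
          add_sp(cx, s$comp, "complex")
          add_rx(lig, paste0(r, "_", s$tag), cx, p("kon_N"), p("koff_N"))
        }
        ## tertiary VEGF.R2.NRP1, reachable from either binary complex
        cx3 <- paste0(v$name, "_R2N1_", s$tag)
        add_sp(cx3, s$comp, "complex")
        add_rx(paste0(v$name, "_R2_", s$tag), paste0("N1_", s$tag), cx3,
               p("kon_c"), p("koff_c"))
        add_rx(paste0(v$name, "_N1_", s$tag), paste0("R2_", s$tag), cx3,
               p("kon_c"), p("koff_c"))
      }
    }
  }

  ## soluble binding per compartment: sVEGFR1 sequestration and (blood)
  ## alpha-2-macroglobulin; bevacizumab binds human isoforms only
  for (co in compartments$name) {
    ct <- .ctag(co)
    for (j in seq_len(nrow(isoforms))) {
      v <- isoforms[j, ]
      lig <- paste0(v$name, "_", ct)
      cx <- paste0(v$name, "_sR1_", ct)
      add_sp(cx, co, "complex")
      add_rx(lig, paste0("sR1_", ct), cx, p("kon_sR1"), p("koff_sR1"))
      if (co == "blood") {
        cx <- paste0(v$name, "_a2m_b")
        add_sp(cx, co, "complex")
        add_rx(lig, "a2m_b", cx, p("kon_a2m"), p("koff_a2m"))
      }
      if (v$human) {
        cx <- paste0(v$name, "_bev_", ct)
        add_sp(cx, co, "complex")
        add_rx(lig, paste0("bev_", ct), cx, p("kon_bev"), p("koff_bev"))
      }
    }
  }

  ## transport of diffusible species
  diffusible <- c(isoforms$name, "sR1", "bev")
  for (d in diffusible) {
    dn <- function(co) paste0(d, "_", .ctag(co))
    add_tr(dn("normal"), "normal", "blood", "permeability", p("ps_normal"))
    add_tr(dn("blood"), "blood", "normal", "permeability", p("ps_normal"))
    add_tr(dn("tumour"), "tumour", "blood", "permeability", p("ps_tumour"),
           vscale = TRUE)
    add_tr(dn("blood"), "blood", "tumour", "permeability", p("ps_tumour"),
           vscale = TRUE)
    add_tr(dn("normal"), "normal", "blood", "lymph_flow", p("lymph_normal"))
    add_tr(dn("tumour"), "tumour", "blood", "lymph_flow", p("lymph_tumour"),
           vscale = TRUE)
  }

  ## plasma clearance (conductance = k_clear * blood volume)
  vb <- p("vol_blood")
  for (v in isoforms$name)
    add_tr(paste0(v, "_b"), "blood", NA, "clearance", p("clear_vegf") * vb)
  add_tr("sR1_b", "blood", NA, "clearance", p("clear_sR1") * vb)
  add_tr("bev_b", "blood", NA, "clearance", p("clear_bev") * vb)
  for (v in c("hv121", "hv165"))
    add_tr(paste0(v, "_bev_b"), "blood", NA, "clearance",
           p("clear_bev") * vb)
  for (v in isoforms$name) {
    add_tr(paste0(v, "_a2m_b"), "blood", NA, "clearance",
           p("clear_cplx") * vb)
    add_tr(paste0(v, "_sR1_b"), "blood", NA, "clearance",
           p("clear_cplx") * vb)
  }

  ## secretion sources
  add_tr("hv121_t", NA, "tumour", "secretion", p("q_hv121_t"), vscale = TRUE)
  add_tr("hv165_t", NA, "tumour", "secretion", p("q_hv165_t"), vscale = TRUE)
  add_tr("mv120_t", NA, "tumour", "secretion", p("q_mv120_t"), vscale = TRUE)
  add_tr("mv164_t", NA, "tumour", "secretion", p("q_mv164_t"), vscale = TRUE)
  add_tr("sR1_t", NA, "tumour", "secretion", p("q_sR1_t"), vscale = TRUE)
  add_tr("mv120_n", NA, "normal", "secretion", p("q_mv120_n"))
  add_tr("mv164_n", NA, "normal", "secretion", p("q_mv164_n"))
  add_tr("sR1_n", NA, "normal", "secretion", p("q_sR1_n"))
  add_tr("mv164_b", NA, "blood", "secretion", p("q_mv164_b"))

  ## pro-angiogenic signal: VEGF-bound VEGFR1/VEGFR2 complexes on the
  ## tumour abluminal endothelium (with or without neuropilin)
  signal <- c(paste0(isoforms$name, "_R1_tab"),
              paste0(isoforms$name, "_R2_tab"),
              paste0(isoforms$name[isoforms$heparin], "_R2N1_tab"))

  vegf_model(compartments = compartments,
             species = do.call(rbind, sp),
             reactions = do.call(rbind, rx),
             transports = do.call(rbind, tr),
             signal_complexes = signal,
             params = config,
             interstitial_fraction = p("interstitial_fraction"))
}

.ctag <- function(comp) c(normal = "n", blood = "b", tumour = "t")[[comp]]

#' Angiogenic signal of a model state
#'
#' Sums the concentrations of the model's signal complexes (VEGF-bound
#' VEGFR1/VEGFR2 on the tumour endothelium). Blood- and
#' normal-compartment complexes never contribute.
#'
#' @param state named numeric state vector (species concentrations,
#'   optionally with a trailing volume element), or an unnamed vector of
#'   length `nrow(model$species)` (+1).
#' @param model a `vegf_model`.
#' @return scalar signal (mol/cm^3).
#' @export
compute_angiogenic_signal <- function(state, model) {
  nsp <- nrow(model$species)
  if (!is.null(names(state))) {
    idx <- match(model$signal_complexes, names(state))
    if (anyNA(idx))
      .schema_error("state is missing signal species: %s",
                    paste(model$signal_complexes[is.na(idx)], collapse = ", "))
  } else {
    if (length(state) < nsp)
      .schema_error("state dimension %d does not match model (%d species)",
                    length(state), nsp)
    idx <- match(model$signal_complexes, model$species$name)
  }
  sum(state[idx])
}

#' Constituent composition of every species
#'
#' Resolves, from the reaction structure, how many copies of each base
#' (non-complex) species every species contains. Used by the
#' conservation checks: with secretion, clearance and transport off,
#' `composition %*% (conc * fluid volume)` is constant along any
#' trajectory.
#'
#' @param model a `vegf_model`.
#' @return matrix (base species x all species) of constituent counts.
#' @export
composition_matrix <- function(model) {
  sp <- model$species$name
  base <- sp[model$species$kind != "complex"]
  comp <- matrix(0, nrow = length(base), ncol = length(sp),
                 dimnames = list(base, sp))
  comp[cbind(base, base)] <- 1
  resolved <- model$species$kind != "complex"
  names(resolved) <- sp
  rx <- model$reactions
  repeat {
    progressed <- FALSE
    for (i in seq_len(nrow(rx))) {
      if (!resolved[rx$c[i]] && resolved[rx$a[i]] && resolved[rx$b[i]]) {
        comp[, rx$c[i]] <- comp[, rx$a[i]] + comp[, rx$b[i]]
        resolved[rx$c[i]] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  if (!all(resolved))
    .schema_error("complex composition unresolved for: %s",
                  paste(sp[!resolved], collapse = ", "))
  comp
}
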