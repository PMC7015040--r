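#' @useDynLib prcgait, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Muscle names, in model order
#'
#' Nine principal muscles per leg: six uniarticular (IL hip flexor, GM hip
#' extensor, VA knee extensor, BFS knee flexor, TA ankle dorsiflexor, SO
#' ankle plantarflexor) and three biarticular (RF hip flexion + knee
#' extension, BFL hip extension + knee flexion, GC knee flexion + ankle
#' extension).
#' @export
muscle_names <- function() {
  c("IL", "GM", "VA", "BFS", "TA", "SO", "RF", "BFL", "GC")
}

#' Generalized coordinate names
#'
#' Order used throughout: trunk translation (x forward, z up), trunk pitch
#' theta (CCW positive, 0 = upright), then hip/knee/ankle of the right leg
#' and hip/knee/ankle of the left leg.  Hip and knee flexion and ankle
#' dorsiflexion are positive.
#' @export
coord_names <- function() {
  c("x", "z", "theta", "hip_r", "knee_r", "ankle_r",
    "hip_l", "knee_l", "ankle_l")
}

# canonical key sets, used both for validation and (de)serialization
.schema <- list(
  body = c("m_trunk", "m_thigh", "m_shank", "m_foot", "I_trunk", "I_thigh",
           "I_shank", "I_foot", "L_thigh", "L_shank", "c_trunk", "c_thigh",
           "c_shank", "foot_com_x", "foot_com_z", "d_toe", "d_heel",
           "sole_z", "inner_offset", "g"),
  joints = c("visc_hip", "visc_knee", "visc_ankle", "k_limit", "c_limit",
             "knee_lo", "knee_hi", "ankle_lo", "ankle_hi"),
  contact = c("k_normal", "c_normal", "k_tangent", "c_tangent",
              "mu_tangent"),
  muscle_cols = c("Fmax", "lopt", "vmax_factor", "kpe", "r_hip", "r_knee",
                  "r_ankle"),
  muscles_scalar = c("T_act", "fl_width", "fv_shape", "fv_ecc"),
  ctrl = c("cycle_period", "K_phi", "phi_fc", "tau_fc", "resetting", "Phi",
           "dPhi", "Lambda", "weights", "kappa_IL", "kappa_GM", "sigma_IL",
           "sigma_GM", "lambda_TA", "lambda_SO", "theta_ref", "v_ref",
           "tau_reg"),
  belt = c("nu"),
  sim = c("dt", "log_dt", "warmup", "fall_frac")
)

#' Default model configuration (nominal 1.3 m/s treadmill preset)
#'
#' Motor-control parameters (pulse onsets/durations, synergy weights,
#' oscillator frequency and coupling, reset phase, regulation gains and
#' delays) are the nominal treadmill set for a 1.3 m/s belt.  Segment
#' parameters follow standard anthropometry for a 60 kg, 1.70 m adult
#' (Winter's proportions); muscle constants and moment arms are
#' literature-standard values for sagittal-plane walking models.  Contact
#' stiffness gives sub-centimetre penetration at body weight.
#'
#' @return nested configuration list (see [validate_config()])
#' @export
default_config <- function() {
  mus <- matrix(c(
    # Fmax   lopt  vmax_factor  kpe    r_hip  r_knee r_ankle
    2600,  0.20, 12, 2000,  0.10,  0.00,  0.00,   # IL
    2000,  0.20, 12, 2000, -0.10,  0.00,  0.00,   # GM
    4600,  0.12, 12, 3000,  0.00, -0.05,  0.00,   # VA
     450,  0.12, 12, 1000,  0.00,  0.05,  0.00,   # BFS
    3000,  0.08, 12, 6000,  0.00,  0.00,  0.04,   # TA
    2800,  0.06, 10, 4000,  0.00,  0.00, -0.05,   # SO
    2000,  0.25, 12, 2000,  0.08, -0.05,  0.00,   # RF
    1200,  0.25, 12, 2000, -0.08,  0.05,  0.00,   # BFL
    1200,  0.10, 10, 2500,  0.00,  0.05, -0.05),  # GC
    nrow = 9, byrow = TRUE,
    dimnames = list(muscle_names(), .schema$muscle_cols))
  W <- matrix(0, 9, 5, dimnames = list(muscle_names(), NULL))
  W["VA", 1] <- 0.42; W["TA", 1] <- 0.35
  W["SO", 2] <- 1.26; W["GC", 2] <- 0.87
  W["IL", 3] <- 1.02; W["BFS", 3] <- 1.09; W["RF", 3] <- 0.10
  W["VA", 4] <- 0.17; W["TA", 4] <- 0.21
  W["GM", 5] <- 0.61; W["BFS", 5] <- 0.20; W["BFL", 5] <- 0.20
  list(
    schema_version = 1L,
    preset = "nominal",
    body = list(
      m_trunk = 40.68, m_thigh = 6.0, m_shank = 2.79, m_foot = 0.87,
      I_trunk = 6.0, I_thigh = 0.105, I_shank = 0.045, I_foot = 0.013,
      L_thigh = 0.41, L_shank = 0.42,
      c_trunk = 0.32, c_thigh = 0.178, c_shank = 0.182,
      foot_com_x = 0.05, foot_com_z = -0.035,
      d_toe = 0.19, d_heel = 0.065, sole_z = 0.07, inner_offset = 0.04,
      g = 9.81),
    joints = list(
      visc_hip = 1.0, visc_knee = 0.6, visc_ankle = 0.3,
      k_limit = 3000, c_limit = 100,
      knee_lo = -0.15, knee_hi = 2.5, ankle_lo = -0.7, ankle_hi = 0.7),
    contact = list(
      k_normal = 100000, c_normal = 1500,
      k_tangent = 50000, c_tangent = 1000, mu_tangent = 1.0),
    muscles = list(
      table = mus, T_act = 0.06, fl_width = 0.40, fv_shape = 0.25,
      fv_ecc = 1.5),
    ctrl = list(
      cycle_period = 1.0,       # omega = 2*pi / cycle_period
      K_phi = 1.7, phi_fc = 0.36, tau_fc = 0.05, resetting = TRUE,
      Phi = c(6.12, 1.48, 2.56, 3.51, 5.38),
      dPhi = c(0.70, 0.90, 0.90, 1.07, 0.96),
      Lambda = c(1.0, 1.0, 1.0, 1.0, 1.0),
      weights = W,
      kappa_IL = -1.0, kappa_GM = 2.0, sigma_IL = -0.20, sigma_GM = 0.40,
      lambda_TA = -0.20, lambda_SO = 0.12,
      theta_ref = -0.012, v_ref = 0.1, tau_reg = 0.08),
    belt = list(nu = 1.3),
    sim = list(dt = 5e-5, log_dt = 0.002, warmup = 0.3, fall_frac = 0.6))
}

#' Built-in experiment presets
#'
#' `"nominal"` is the 1.3 m/s treadmill parameter set.  `"belt_plus"` and
#' `"belt_minus"` are the parameter sets for belt speeds increased and
#' decreased by 0.02 m/s, which change only the second pulse onset, the
#' oscillator period, the five pulse amplitudes, and the reset phase.
#'
#' @param name one of `"nominal"`, `"belt_plus"`, `"belt_minus"`
#' @return a full configuration list
#' @export
gait_preset <- function(name = c("nominal", "belt_plus", "belt_minus")) {
  name <- match.arg(name)
  cfg <- default_config()
  if (name == "belt_plus") {
    cfg$preset <- "belt_plus"
    cfg$belt$nu <- 1.32
    cfg$ctrl$Phi[2] <- 1.46
    cfg$ctrl$cycle_period <- 0.9
    cfg$ctrl$Lambda <- c(1.04, 1.14, 1.10, 1.03, 1.18)
    cfg$ctrl$phi_fc <- 0.48
  } else if (name == "belt_minus") {
    cfg$preset <- "belt_minus"
    cfg$belt$nu <- 1.28
    cfg$ctrl$Phi[2] <- 1.50
    cfg$ctrl$cycle_period <- 1.1
    cfg$ctrl$Lambda <- c(0.96, 0.90, 0.90, 0.98, 0.82)
    cfg$ctrl$phi_fc <- 0.04
  }
  cfg
}

#' Validate a configuration list
#'
#' Checks the key sets of every section (missing and unknown keys are both
#' errors), positivity of masses, lengths, inertias, pulse durations and
#' time constants, non-negativity of synergy weights and contact/limit
#' constants, ordering of joint limits, and the structural-zero pattern of
#' the regulation gains.
#'
#' @param cfg configuration list
#' @return `cfg`, invisibly, if valid; otherwise an error naming the field
#' @export
validate_config <- function(cfg) {
  chk_keys <- function(x, keys, where) {
    missing <- setdiff(keys, names(x))
    extra <- setdiff(names(x), keys)
    if (length(missing))
      stop(sprintf("config %s: missing key(s) %s", where,
                   paste(missing, collapse = ", ")), call. = FALSE)
    if (length(extra))
      stop(sprintf("config %s: unknown key(s) %s", where,
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  chk_keys(cfg, c("schema_version", "preset", "body", "joints", "contact",
                  "muscles", "ctrl", "belt", "sim"), "top level")
  if (cfg$schema_version != 1L)
    stop("unsupported config schema_version", call. = FALSE)
  chk_keys(cfg$body, .schema$body, "body")
  chk_keys(cfg$joints, .schema$joints, "joints")
  chk_keys(cfg$contact, .schema$contact, "contact")
  chk_keys(cfg$muscles, c("table", .schema$muscles_scalar), "muscles")
  chk_keys(cfg$ctrl, .schema$ctrl, "ctrl")
  chk_keys(cfg$belt, .schema$belt, "belt")
  chk_keys(cfg$sim, .schema$sim, "sim")
  b <- cfg$body
  pos <- c("m_trunk", "m_thigh", "m_shank", "m_foot", "I_trunk", "I_thigh",
           "I_shank", "I_foot", "L_thigh", "L_shank", "sole_z", "g")
  for (k in pos)
    if (b[[k]] <= 0) stop(sprintf("body$%s must be positive", k),
                          call. = FALSE)
  if (b$inner_offset <= 0 || b$d_toe - b$inner_offset <=
        -(b$d_heel - b$inner_offset))
    stop("body: inner contact points must lie inside the toe-heel span",
         call. = FALSE)
  j <- cfg$joints
  if (j$knee_lo >= j$knee_hi) stop("joints: knee_lo must be < knee_hi",
                                   call. = FALSE)
  if (j$ankle_lo >= j$ankle_hi) stop("joints: ankle_lo must be < ankle_hi",
                                     call. = FALSE)
  for (k in c("visc_hip", "visc_knee", "visc_ankle", "k_limit", "c_limit"))
    if (j[[k]] < 0) stop(sprintf("joints$%s must be non-negative", k),
                         call. = FALSE)
  for (k in .schema$contact)
    if (cfg$contact[[k]] < 0)
      stop(sprintf("contact$%s must be non-negative", k), call. = FALSE)
  m <- cfg$muscles$table
  if (!is.matrix(m) || nrow(m) != 9 || ncol(m) != 7 ||
      !identical(rownames(m), muscle_names()))
    stop("muscles$table must be a 9 x 7 matrix with canonical row names",
         call. = FALSE)
  if (any(m[, c("Fmax", "lopt", "vmax_factor")] <= 0))
    stop("muscle Fmax, lopt, vmax_factor must be positive", call. = FALSE)
  if (any(m[, "kpe"] < 0))
    stop("muscle passive stiffness must be non-negative", call. = FALSE)
  n_arms <- rowSums(m[, c("r_hip", "r_knee", "r_ankle")] != 0)
  uni <- c("IL", "GM", "VA", "BFS", "TA", "SO")
  if (any(n_arms[uni] != 1))
    stop("uniarticular muscles must have exactly one nonzero moment arm",
         call. = FALSE)
  if (any(n_arms[c("RF", "BFL", "GC")] != 2))
    stop("biarticular muscles must have exactly two nonzero moment arms",
         call. = FALSE)
  if (cfg$muscles$T_act <= 0) stop("muscles$T_act must be positive",
                                   call. = FALSE)
  ct <- cfg$ctrl
  if (ct$cycle_period <= 0) stop("ctrl$cycle_period must be positive",
                                 call. = FALSE)
  if (ct$tau_fc < 0 || ct$tau_reg < 0)
    stop("ctrl delays must be non-negative", call. = FALSE)
  if (ct$phi_fc < 0 || ct$phi_fc >= 2 * pi)
    stop("ctrl$phi_fc must lie in [0, 2*pi)", call. = FALSE)
  if (length(ct$Phi) != 5 || length(ct$dPhi) != 5 || length(ct$Lambda) != 5)
    stop("ctrl$Phi, dPhi, Lambda must have length 5", call. = FALSE)
  if (any(ct$dPhi <= 0)) stop("ctrl$dPhi must be positive", call. = FALSE)
  W <- ct$weights
  if (!is.matrix(W) || nrow(W) != 9 || ncol(W) != 5)
    stop("ctrl$weights must be a 9 x 5 matrix", call. = FALSE)
  if (any(W < 0)) stop("synergy weights must be non-negative", call. = FALSE)
  if (cfg$belt$nu <= 0) stop("belt$nu must be positive", call. = FALSE)
  s <- cfg$sim
  if (s$dt <= 0) stop("sim$dt must be positive", call. = FALSE)
  if (s$log_dt < s$dt) stop("sim$log_dt must be >= sim$dt", call. = FALSE)
  invisible(cfg)
}

# Assemble the flat parameter list consumed by the compiled core.
# `resetting` overrides the config flag (the ablation switch).
cpp_params <- function(cfg, resetting = NULL) {
  validate_config(cfg)
  ct <- cfg$ctrl
  if (is.null(resetting)) resetting <- isTRUE(ct$resetting)
  kap <- sig <- lam <- stats::setNames(numeric(9), muscle_names())
  kap["IL"] <- ct$kappa_IL; kap["GM"] <- ct$kappa_GM
  sig["IL"] <- ct$sigma_IL; sig["GM"] <- ct$sigma_GM
  lam["TA"] <- ct$lambda_TA; lam["SO"] <- ct$lambda_SO
  list(
    body = cfg$body,
    joints = cfg$joints,
    contact = cfg$contact,
    muscles = list(table = cfg$muscles$table, T_act = cfg$muscles$T_act,
                   fl_width = cfg$muscles$fl_width,
                   fv_shape = cfg$muscles$fv_shape,
                   fv_ecc = cfg$muscles$fv_ecc),
    ctrl = list(
      omega = 2 * pi / ct$cycle_period, K_phi = ct$K_phi,
      phi_fc = ct$phi_fc, tau_fc = ct$tau_fc,
      resetting = as.integer(resetting),
      Phi = ct$Phi, dPhi = ct$dPhi, Lambda = ct$Lambda, W = ct$weights,
      kappa = kap, sigma = sig, lambda = lam,
      theta_ref = ct$theta_ref, v_ref = ct$v_ref, tau_reg = ct$tau_reg))
}

#' Write a configuration to YAML or JSON
#'
#' @param cfg configuration list
#' @param path output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`)
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  ser <- cfg
  ser$muscles$table <- apply(cfg$muscles$table, 1, as.list, simplify = FALSE)
  ser$muscles$table <- lapply(ser$muscles$table, function(r)
    stats::setNames(r, .schema$muscle_cols))
  ser$ctrl$weights <- lapply(seq_len(9), function(i)
    as.numeric(cfg$ctrl$weights[i, ]))
  names(ser$ctrl$weights) <- muscle_names()
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(ser, precision = 15), path)
  }
  invisible(path)
}

#' Load and validate a configuration from YAML or JSON
#'
#' @param path file written by [write_config()] (or hand-edited in the same
#'   schema)
#' @return validated configuration list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  tab <- cfg$muscles$table
  m <- matrix(0, 9, 7, dimnames = list(muscle_names(), .schema$muscle_cols))
  for (mn in muscle_names())
    m[mn, ] <- as.numeric(unlist(tab[[mn]])[.schema$muscle_cols])
  cfg$muscles$table <- m
  W <- do.call(rbind, lapply(cfg$ctrl$weights[muscle_names()], as.numeric))
  rownames(W) <- muscle_names()
  cfg$ctrl$weights <- W
  cfg$schema_version <- as.integer(cfg$schema_version)
  for (sec in c("ctrl"))
    cfg[[sec]]$resetting <- isTRUE(cfg[[sec]]$resetting)
  for (v in c("Phi", "dPhi", "Lambda"))
    cfg$ctrl[[v]] <- as.numeric(cfg$ctrl[[v]])
  validate_config(cfg)
  cfg
}

#' Hash of a configuration (for run manifests)
#'
#' Deterministic digest of the serialized configuration; changes iff any
#' configuration value changes.
#' @param cfg configuration list
#' @return character scalar
#' @export
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # simple polynomial rolling hash; avoids an external digest dependency
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 268435399
  sprintf("%07x", h)
}
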