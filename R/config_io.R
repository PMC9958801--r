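# unit multipliers to the unit each constructor expects (SI, except the
# valley separation which is kept in eV)
.unit_table <- c(
  "m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6, "nm" = 1e-9,
  "V" = 1, "mV" = 1e-3,
  "K" = 1,
  "eV" = 1,
  "M" = 1, "mol/L" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6,
  "nM" = 1e-9, "pM" = 1e-12, "fM" = 1e-15,
  "m^-2" = 1, "cm^-2" = 1e4,
  "m^-3" = 1, "cm^-3" = 1e6,
  "F/m^2" = 1, "uF/cm^2" = 1e-2, "µF/cm^2" = 1e-2,
  "M^-1" = 1, "1/M" = 1, "L/mol" = 1,
  "m^2/Vs" = 1, "cm^2/Vs" = 1e-4
)

#' Parse a value-with-unit into model units
#'
#' Accepts a bare number (taken as already being in model units: SI, with
#' the valley separation in eV) or a string such as `"30 nm"`,
#' `"4e14 cm^-2"`, `"20 uF/cm^2"`, `"100 fM"`.
#'
#' @param x A number, or a string `"<value> <unit>"`.
#' @param field Field name used in error messages.
#' @return A single numeric value in model units.
#' @examples
#' parse_quantity("30 nm")       # 3e-8
#' parse_quantity("4e14 cm^-2")  # 4e18
#' @export
parse_quantity <- function(x, field = "value") {
  if (is.numeric(x)) {
    .assert(length(x) == 1L && is.finite(x),
            sprintf("`%s` must be a single finite number", field))
    return(as.numeric(x))
  }
  .assert(is.character(x) && length(x) == 1L,
          sprintf("`%s` must be a number or a '<value> <unit>' string", field))
  parts <- strsplit(trimws(x), "\\s+")[[1]]
  val <- suppressWarnings(as.numeric(parts[1]))
  .assert(is.finite(val), sprintf("cannot parse the numeric part of `%s` ('%s')", field, x))
  if (length(parts) == 1L) return(val)
  unit <- paste(parts[-1], collapse = " ")
  if (!unit %in% names(.unit_table)) {
    abort(sprintf("unknown unit '%s' in `%s`; known units: %s",
                  unit, field, paste(names(.unit_table), collapse = ", ")))
  }
  val * .unit_table[[unit]]
}

#' Reference MoS2 BioFET parameter set
#'
#' The full parameter set of the modeled monolayer-MoS2 device: a 20 um x
#' 5 um channel under a 30 nm HfO2 barrier oxide (eps_rel 25) on 270 nm
#' SiO2 (eps_rel 3.9), two-valley n-type band structure (m1 = 0.54 m0,
#' m2 = 0.58 m0, g1 = 2, g2 = 6, dE12 = 0.07 eV), mobility 20 cm^2/Vs,
#' gate offsets Vgo = 0.48 V and Vbo = 0, electrolyte with eps 80 eps0,
#' Stern capacitance 20 uF/cm^2, 1 mM ionic strength, amphoteric HfO2
#' surface with pKa = pKb = 7 and 4e14 sites/cm^2, and biotin-streptavidin
#' membrane defaults (Nr = 2.3e13 cm^-2, Kc = 1e13 1/M, hm = 5 nm,
#' Nt = 100 fM). Arguments override the study knobs that the reference
#' experiments vary.
#'
#' @param pH Bulk pH (default 5).
#' @param i0 Ionic molar concentration, mol/L (default 1e-3).
#' @param Ns Surface site density, 1/m^2 (default 4e18, the bare-oxide
#'   value; the functionalized surface reduces it to 1 percent, 4e16).
#' @param membrane A [membrane_spec()]; default `membrane_spec(Nm = 0)`
#'   (ion sensing, no bound macromolecules).
#' @param temperature Temperature, K (default 300).
#' @return A [biofet_config()].
#' @examples
#' cfg <- preset_table1(pH = 3)
#' cfg$device$L # 5e-6 m
#' @export
preset_table1 <- function(pH = 5, i0 = 1e-3, Ns = 4e18,
                          membrane = membrane_spec(Nm = 0),
                          temperature = 300) {
  th <- thermal_state(temperature)
  band <- band_structure("n", m1_rel = 0.54, m2_rel = 0.58, g1 = 2, g2 = 6,
                         dE12 = 0.07)
  dev <- device_params(
    W = 20e-6, L = 5e-6, t_tox = 30e-9, eps_tox_rel = 25,
    t_box = 270e-9, eps_box_rel = 3.9, Vgo = 0.48, Vbo = 0, mu = 20e-4,
    sheet = sheet_charge_model(band, th))
  biofet_config(
    device = dev,
    electrolyte = electrolyte_spec(i0 = i0, eps_w_rel = 80, eps_m_rel = 80,
                                   C_stern = 0.20, thermal = th),
    site_binding = site_binding_spec(Ns = Ns, pKa = 7, pKb = 7, pH = pH),
    membrane = membrane)
}

#' Langmuir membrane preset for streptavidin sensing
#'
#' Convenience wrapper for the biotin-streptavidin membrane: receptor
#' density 2.3e13 cm^-2, binding constant 1e13 1/M, membrane thickness
#' 5 nm; target concentration and per-molecule charge are study-specific.
#'
#' @param Nt Streptavidin molar concentration, mol/L.
#' @param kq Signed charges per bound molecule (e.g. +22.3 at pH 3,
#'   -15.2 at pH 9, from protein protonation calculations).
#' @param Nr Receptor density, 1/m^2.
#' @param Kc Binding constant, L/mol.
#' @param hm Membrane thickness, m.
#' @return A [membrane_spec()] in Langmuir mode.
#' @export
streptavidin_membrane <- function(Nt, kq, Nr = 2.3e17, Kc = 1e13, hm = 5e-9) {
  membrane_spec(Nr = Nr, Nt = Nt, Kc = Kc, hm = hm, kq = kq)
}

.known_keys <- list(
  device = c("W", "L", "t_tox", "eps_tox_rel", "t_box", "eps_box_rel",
             "Vgo", "Vbo", "mu"),
  band = c("carrier_type", "m1_rel", "m2_rel", "g1", "g2", "dE12"),
  thermal = "temperature",
  electrolyte = c("i0", "eps_w_rel", "eps_m_rel", "C_stern"),
  site_binding = c("Ns", "pKa", "pKb", "pH"),
  membrane = c("Nm", "Nr", "Nt", "Kc", "hm", "kq"),
  sweeps = NULL
)

.check_keys <- function(section, values) {
  unknown <- setdiff(names(values), .known_keys[[section]])
  if (length(unknown) > 0) {
    abort(sprintf("unknown field(s) in `%s`: %s", section,
                  paste(unknown, collapse = ", ")))
  }
}

.pq <- function(lst, key, default = NULL) {
  if (is.null(lst[[key]])) return(default)
  parse_quantity(lst[[key]], key)
}

#' Load a study configuration from YAML
#'
#' Reads a human-editable YAML file with sections `device`, `band`,
#' `thermal`, `electrolyte`, `site_binding`, `membrane` and optionally
#' `sweeps`. Every numeric field may be a bare number (model units) or a
#' `"<value> <unit>"` string (e.g. `t_tox: "30 nm"`, `Ns: "4e14 cm^-2"`);
#' missing fields fall back to the reference MoS2 device values and each
#' applied default is reported as a message. Unknown fields, unknown units
#' and contradictory membrane descriptions (both a fixed `Nm` and Langmuir
#' parameters) are errors.
#'
#' @param path Path to a YAML file.
#' @param quiet Suppress the applied-defaults message.
#' @return A [biofet_config()] (with any `sweeps` list attached).
#' @seealso [write_config()], [run_study()]
#' @export
load_config <- function(path, quiet = FALSE) {
  .assert(file.exists(path), sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(.known_keys))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config section(s): %s", paste(unknown, collapse = ", ")))
  }
  for (s in intersect(names(raw), names(.known_keys))) {
    if (s != "sweeps") .check_keys(s, raw[[s]])
  }
  ref <- preset_table1()
  defaults_used <- character(0)
  take <- function(section, key, ref_value) {
    v <- .pq(raw[[section]], key)
    if (is.null(v)) {
      defaults_used <<- c(defaults_used, sprintf("%s.%s = %g", section, key, ref_value))
      ref_value
    } else v
  }

  th <- thermal_state(take("thermal", "temperature", 300))
  ct <- raw$band$carrier_type %||% "n"
  band <- band_structure(ct,
                         m1_rel = take("band", "m1_rel", 0.54),
                         m2_rel = take("band", "m2_rel", 0.58),
                         g1 = take("band", "g1", 2),
                         g2 = take("band", "g2", 6),
                         dE12 = take("band", "dE12", 0.07))
  dev <- device_params(
    W = take("device", "W", ref$device$W),
    L = take("device", "L", ref$device$L),
    t_tox = take("device", "t_tox", ref$device$t_tox),
    eps_tox_rel = take("device", "eps_tox_rel", 25),
    t_box = take("device", "t_box", ref$device$t_box),
    eps_box_rel = take("device", "eps_box_rel", 3.9),
    Vgo = take("device", "Vgo", 0.48),
    Vbo = take("device", "Vbo", 0),
    mu = take("device", "mu", 20e-4),
    sheet = sheet_charge_model(band, th))
  elec <- electrolyte_spec(
    i0 = take("electrolyte", "i0", 1e-3),
    eps_w_rel = take("electrolyte", "eps_w_rel", 80),
    eps_m_rel = take("electrolyte", "eps_m_rel", 80),
    C_stern = take("electrolyte", "C_stern", 0.20),
    thermal = th)
  site <- site_binding_spec(
    Ns = take("site_binding", "Ns", 4e18),
    pKa = take("site_binding", "pKa", 7),
    pKb = take("site_binding", "pKb", 7),
    pH = take("site_binding", "pH", 5))
  m <- raw$membrane
  mem <- if (is.null(m)) {
    defaults_used <- c(defaults_used, "membrane.Nm = 0")
    membrane_spec(Nm = 0)
  } else {
    membrane_spec(Nm = .pq(m, "Nm"), Nr = .pq(m, "Nr"), Nt = .pq(m, "Nt"),
                  Kc = .pq(m, "Kc"), hm = .pq(m, "hm"), kq = .pq(m, "kq"))
  }
  if (!quiet && length(defaults_used) > 0) {
    message("applied defaults: ", paste(defaults_used, collapse = "; "))
  }
  biofet_config(dev, elec, site, mem, sweeps = raw$sweeps %||% list())
}

#' Write a configuration to YAML in normalized model units
#'
#' Inverse of [load_config()]: all quantities are written as bare numbers in
#' model units (SI; valley separation in eV), so
#' `load_config(write_config(cfg, f))` reproduces `cfg`.
#'
#' @param config A [biofet_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  .assert(inherits(config, "biofet_config"), "`config` must be a biofet_config")
  d <- config$device; b <- d$sheet$band; e <- config$electrolyte
  s <- config$site_binding; m <- config$membrane
  out <- list(
    device = list(W = d$W, L = d$L, t_tox = d$t_tox,
                  eps_tox_rel = d$eps_tox / .const$eps0,
                  t_box = d$t_box, eps_box_rel = d$eps_box / .const$eps0,
                  Vgo = d$Vgo, Vbo = d$Vbo, mu = d$mu),
    band = list(carrier_type = b$carrier_type, m1_rel = b$m1_rel,
                m2_rel = b$m2_rel, g1 = b$g1, g2 = b$g2, dE12 = b$dE12),
    thermal = list(temperature = d$sheet$thermal$temperature),
    electrolyte = list(i0 = e$i0, eps_w_rel = e$eps_w / .const$eps0,
                       eps_m_rel = e$eps_m / .const$eps0, C_stern = e$C_stern),
    site_binding = list(Ns = s$Ns, pKa = s$pKa, pKb = s$pKb, pH = s$pH),
    membrane = if (m$mode == "fixed_Nm") list(Nm = m$Nm) else
      list(Nr = m$Nr, Nt = m$Nt, Kc = m$Kc, hm = m$hm, kq = m$kq)
  )
  if (length(config$sweeps) > 0) out$sweeps <- config$sweeps
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

.iv_units <- c(Vlg = "V", Vb = "V", Vs = "V", Vd = "V", psi0 = "V",
               phi_ch_s = "V", phi_ch_d = "V", us = "1", ud = "1", Ids = "A",
               pH = "1", Nm = "1/m^3", i0 = "mol/L", Nt = "mol/L")

#' Export a sweep as annotated CSV
#'
#' Comma-separated, '.' decimal, with '#'-prefixed header comments naming
#' the column units. Values are written with 17 significant digits so that
#' re-importing reproduces the in-memory doubles exactly.
#'
#' @param curve A tibble (e.g. a `biofet_iv` sweep).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_iv_csv <- function(curve, path) {
  cols <- names(curve)
  units <- ifelse(cols %in% names(.iv_units), .iv_units[cols], "1")
  header <- c("# biofet2d sweep export",
              sprintf("# column units: %s",
                      paste(sprintf("%s [%s]", cols, units), collapse = ", ")))
  fmt_cell <- function(x) {
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  }
  body <- do.call(paste, c(lapply(curve, fmt_cell), sep = ","))
  writeLines(c(header, paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' Read a sweep exported by [write_iv_csv()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_iv_csv <- function(path) {
  as_tibble(utils::read.csv(path, comment.char = "#"))
}

.sweep_grid <- function(sw, key, default_min, default_max, default_n = 201) {
  if (!is.null(sw[[key]])) return(as.numeric(sw[[key]]))
  lo <- .pq(sw, paste0(key, "_min"), default_min)
  hi <- .pq(sw, paste0(key, "_max"), default_max)
  n <- .pq(sw, paste0(key, "_n"), default_n)
  if (is.null(lo) || is.null(hi)) return(NULL)
  seq(lo, hi, length.out = n)
}

#' Run the sweeps requested by a configuration
#'
#' Executes each entry of `config$sweeps` and writes one CSV per sweep
#' (plus a JSON report for `sensitivity` sweeps) into `out_dir`. Supported
#' sweep types and their fields:
#' \describe{
#'   \item{transfer}{`vlg` (vector) or `vlg_min`/`vlg_max`/`vlg_n`; `vds`
#'     (default 1); `vb`.}
#'   \item{output}{`vds` or `vds_min`/`vds_max`/`vds_n`; `vlg`; `vb`.}
#'   \item{ph}{`values` (pH list) plus transfer fields; one combined CSV
#'     with a `pH` column.}
#'   \item{nm}{`values` (fixed membrane charge list, 1/m^3 or
#'     `"... cm^-3"` strings) plus transfer fields.}
#'   \item{salt}{`values` (ionic strengths, mol/L or `"... mM"`).}
#'   \item{titration}{`values` (target concentrations, mol/L or `"... fM"`),
#'     `kq` (required).}
#'   \item{sensitivity}{`nt` (analyte concentration), `kq`; optional
#'     `vds`, `sub_offset`, `on_offset`, `vds_linear`.}
#' }
#'
#' @param config A [biofet_config()] or a path to a YAML config.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a tibble manifest with columns `sweep`, `type`,
#'   `file`.
#' @export
run_study <- function(config, out_dir = ".", quiet = FALSE) {
  if (is.character(config)) config <- load_config(config, quiet = quiet)
  .assert(inherits(config, "biofet_config"), "`config` must be a biofet_config")
  if (length(config$sweeps) == 0) {
    warn("no sweeps requested; nothing to do")
    return(invisible(tibble(sweep = character(), type = character(),
                            file = character())))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- purrr::imap(config$sweeps, function(sw, idx) {
    type <- sw$type %||% abort(sprintf("sweep %d has no `type`", idx))
    name <- sw$name %||% sprintf("sweep%02d_%s", idx, type)
    vds <- .pq(sw, "vds", 1)
    vb <- .pq(sw, "vb", 0)
    vlg <- .sweep_grid(sw, "vlg", NULL, NULL)
    file <- file.path(out_dir, paste0(name, ".csv"))
    res <- switch(
      type,
      transfer = transfer_sweep(config, vlg = vlg, vds = vds, vb = vb),
      output = {
        vds_grid <- .sweep_grid(sw, "vds", 0, 1, 101)
        output_sweep(config, vds = vds_grid, vlg = .pq(sw, "vlg", 1), vb = vb)
      },
      ph = {
        vals <- vapply(sw$values, parse_quantity, numeric(1), field = "values")
        dplyr::bind_rows(lapply(vals, function(ph) {
          cfg <- config
          cfg$site_binding <- site_binding_spec(config$site_binding$Ns,
                                                config$site_binding$pKa,
                                                config$site_binding$pKb, ph)
          dplyr::mutate(transfer_sweep(cfg, vlg = vlg, vds = vds, vb = vb),
                        pH = ph)
        }))
      },
      nm = {
        vals <- vapply(sw$values, parse_quantity, numeric(1), field = "values")
        dplyr::bind_rows(lapply(vals, function(nm) {
          cfg <- config
          cfg$membrane <- membrane_spec(Nm = nm)
          dplyr::mutate(transfer_sweep(cfg, vlg = vlg, vds = vds, vb = vb),
                        Nm = nm)
        }))
      },
      salt = {
        vals <- vapply(sw$values, parse_quantity, numeric(1), field = "values")
        dplyr::bind_rows(lapply(vals, function(i0) {
          cfg <- config
          cfg$electrolyte <- electrolyte_spec(
            i0, config$electrolyte$eps_w / .const$eps0,
            config$electrolyte$eps_m / .const$eps0,
            config$electrolyte$C_stern, config$electrolyte$thermal)
          dplyr::mutate(transfer_sweep(cfg, vlg = vlg, vds = vds, vb = vb),
                        i0 = i0)
        }))
      },
      titration = {
        kq <- .pq(sw, "kq") %||% abort("titration sweep needs `kq`")
        vals <- vapply(sw$values, parse_quantity, numeric(1), field = "values")
        dplyr::bind_rows(lapply(vals, function(nt) {
          cfg <- config
          cfg$membrane <- streptavidin_membrane(Nt = nt, kq = kq)
          dplyr::mutate(transfer_sweep(cfg, vlg = vlg, vds = vds, vb = vb),
                        Nt = nt)
        }))
      },
      sensitivity = {
        kq <- .pq(sw, "kq") %||% abort("sensitivity sweep needs `kq`")
        nt <- .pq(sw, "nt") %||% abort("sensitivity sweep needs `nt`")
        cfg_ref <- config; cfg_ref$membrane <- membrane_spec(Nm = 0)
        cfg_ana <- config
        cfg_ana$membrane <- streptavidin_membrane(Nt = nt, kq = kq)
        rep <- sensing_report(cfg_ref, cfg_ana, vlg = vlg, vds = vds, vb = vb,
                              sub_offset = .pq(sw, "sub_offset", 0.2),
                              on_offset = .pq(sw, "on_offset", 0.5),
                              vds_linear = .pq(sw, "vds_linear", 0.05))
        json <- file.path(out_dir, paste0(name, ".json"))
        write_sensing_report(rep, json)
        say("wrote %s", json)
        rep$report
      },
      abort(sprintf("unknown sweep type '%s'", type))
    )
    write_iv_csv(res, file)
    say("wrote %s", file)
    tibble(sweep = name, type = type, file = file)
  })
  invisible(dplyr::bind_rows(manifest))
}
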