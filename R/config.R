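# Model configuration I/O (YAML / JSON). The bundled config reproduces the
# final compound files: cholesterol (parent) and 4beta-OHC (metabolite) with
# their per-pathway intrinsic clearances, the reference physiology, the
# endogenous infusion regimen and a rifampicin-like perpetrator.

#' Load and validate a model configuration
#'
#' Reads a YAML or JSON configuration describing compounds, default
#' physiology, dose regimens and (optionally) perpetrators, validates every
#' field against the domain-type invariants, and returns a normalized
#' `model_config` object (units h, L, mg, pmol).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `model_config` list with elements `compounds` (named list of
#'   [compound_params()]), `physiology` ([system_physiology()]), `regimens`
#'   (list of [dose_regimen()]) and `perpetrators` (named list with `compound`
#'   and `interaction` entries).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(raw)
}

config_from_list <- function(raw) {
  if (is.null(raw$compounds)) stop_field("compounds", "missing from config")
  compounds <- lapply(raw$compounds, function(cm) {
    cm$pathways <- lapply(cm$pathways, function(p) do.call(pathway_clearance, p))
    do.call(compound_params, cm)
  })
  names(compounds) <- vapply(compounds, `[[`, "", "name")
  phys <- if (is.null(raw$physiology)) default_physiology() else {
    ph <- raw$physiology
    if (!is.null(ph$abundances)) ph$abundances <- unlist(ph$abundances)
    do.call(system_physiology, ph)
  }
  regimens <- lapply(raw$regimens, function(r) do.call(dose_regimen, r))
  perpetrators <- lapply(raw$perpetrators, function(pp) {
    cm <- pp$compound
    cm$pathways <- lapply(cm$pathways, function(p) do.call(pathway_clearance, p))
    list(compound = do.call(compound_params, cm),
         interaction = do.call(interaction_spec, pp$interaction),
         pk = pp$pk)
  })
  if (length(perpetrators)) {
    names(perpetrators) <- vapply(perpetrators, function(p) p$compound$name, "")
  }
  structure(list(compounds = compounds, physiology = phys,
                 regimens = regimens, perpetrators = perpetrators),
            class = "model_config")
}

#' Write a model configuration
#'
#' Serializes a `model_config` back to YAML or JSON so that
#' `load_config(write_config(cfg, f))` round-trips to an identical object.
#'
#' @param config A `model_config`.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(el) {
      if (is.list(el) || inherits(el, c("compound_params", "pathway_clearance",
                                        "system_physiology", "dose_regimen",
                                        "interaction_spec"))) strip(el)
      else if (is.numeric(el) && !is.null(names(el))) as.list(el)
      else el
    })
  }
  raw <- list(
    compounds = lapply(unname(config$compounds), strip),
    physiology = strip(config$physiology),
    regimens = lapply(config$regimens, strip),
    perpetrators = lapply(config$perpetrators, function(pp) {
      list(compound = strip(pp$compound), interaction = strip(pp$interaction),
           pk = pp$pk)
    }))
  drop_null <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, drop_null)
    x[!vapply(x, function(el) is.null(el) || (length(el) == 1L && !is.list(el) && is.na(el)),
              logical(1))]
  }
  raw <- drop_null(raw)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path, precision = 15)
  }
  invisible(path)
}

#' Bundled cholesterol / 4beta-OHC model configuration
#'
#' Loads the default configuration shipped with the package: the final
#' parent and metabolite compound files (optimized CYP3A4 CLint 4.17e-7 with
#' CYP3A5/CYP3A7 siblings, CYP27A1 and residual HLM pathways), reference
#' physiology, the 1.73 mg/kg/day endogenous cholesterol infusion, and a
#' rifampicin-like inducer (Ind_max 16, IndC50 0.32 uM).
#'
#' @return A `model_config`.
#' @export
default_model_config <- function() {
  load_config(system.file("extdata", "cholesterol_4bohc.yaml",
                          package = "ohcpbpk", mustWork = TRUE))
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n  compounds:", paste(names(x$compounds), collapse = ", "),
      "\n  perpetrators:", paste(names(x$perpetrators), collapse = ", "),
      "\n  regimens:", length(x$regimens), "\n")
  invisible(x)
}
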