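#' Read model constants from a YAML configuration file
#'
#' Assembles the model context (physiology, lipid content, congener
#' table, CYP parameters, solver controls) from a structured
#' configuration file.  Every section is optional; omitted sections fall
#' back to the package defaults.  See
#' \code{system.file("extdata", "model_config.yaml", package =
#' "lipidpbtk")} for a complete template.
#'
#' @param path Path to a YAML file.
#' @return List with components \code{phys} (\code{nle_physiology}),
#'   \code{congeners}, \code{cyp} (\code{\link{induction_params}}) and
#'   \code{control} (solver controls).
#' @export
read_model_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_model_config requires the 'yaml' package",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  lip <- do.call(lipid_content,
                 cfg$lipid_content %||% list())
  conv_args <- cfg$physiology %||% list()
  conv_args <- lapply(conv_args, function(x)
    if (is.list(x)) unlist(x) else x)
  conv <- do.call(conventional_physiology, conv_args)
  mix_args <- cfg$congeners %||% list()
  if (!is.null(mix_args$v0)) mix_args$v0 <- unlist(mix_args$v0)
  congeners <- do.call(pcb_mixture, mix_args)
  cyp_args <- cfg$cyp %||% list()
  cyp_args <- lapply(cyp_args, function(x)
    if (is.list(x)) unlist(x) else x)
  cyp <- do.call(induction_params, cyp_args)
  list(phys = scale_to_nle(conv, lip), congeners = congeners,
       cyp = cyp, control = cfg$solver %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
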