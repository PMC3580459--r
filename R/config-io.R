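#' Read a synapse configuration from a YAML file
#'
#' The file mirrors the \code{\link{synapse_config}} fields (units are
#' annotated by the key names: nM, ms, Hz).  Pools are a named map; each
#' pool lists its ligands with \code{role}, \code{kon}, \code{Kd_nM} and
#' optional \code{concentration_nM}.
#'
#' Example:
#' \preformatted{
#' presyn_pool: M2
#' tonic_rate_hz: 7
#' nt_halflife_ms: 5
#' quantal_increment_nM: 6400
#' presyn: {rmax: 0.5, S: 2, B0: 0.5, wf: 0.3, wd: 0.2,
#'          facilitation_halflife_ms: 90, depression_halflife_ms: 120}
#' pools:
#'   M2:
#'     ACh: {role: neurotransmitter, kon: 2.0e-6, Kd_nM: 320}
#'   M1:
#'     ACh: {role: neurotransmitter, kon: 2.0e-6, Kd_nM: 304}
#' }
#'
#' @param path Path to the YAML file.
#' @return A \code{\link{synapse_config}}.
#' @export
read_synapse_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to read config files")
  y <- yaml::read_yaml(path)
  if (is.null(y$pools)) stop("config file has no `pools` section")
  pools <- lapply(names(y$pools), function(pn) {
    lg <- lapply(names(y$pools[[pn]]), function(ln) {
      spec <- y$pools[[pn]][[ln]]
      ligand(ln, role = spec$role, kon = spec$kon, Kd = spec$Kd_nM,
             concentration = spec$concentration_nM %||% 0)
    })
    receptor_pool(lg, name = pn)
  })
  presyn_args <- y$presyn %||% list()
  presyn <- do.call(presynaptic_physiology, presyn_args)
  args <- list(pools = pools, presyn_pool = y$presyn_pool, presyn = presyn)
  for (k in c("tonic_rate_hz", "nt_halflife_ms", "quantal_increment_nM",
              "equilibration_nM", "transient_s", "averaging_s", "dt_ms"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(synapse_config, args)
}
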