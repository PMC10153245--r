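#' Energetic cost of carrying prophages
#'
#' A DNA-replication cost model: cellular maintenance is dominated by
#' replicating DNA, so the ATP spent on prophages is the maintenance
#' budget times the genomic prophage density. With the default inputs --
#' maintenance 0.2e9 ATP/hr (an E. coli estimate), density 0.024 and a
#' 5.1 Mbp genome -- the prophage cost is 4.8e6 ATP/hr, i.e. 0.94 ATP per
#' bp of genome per hour, and the fraction of the cell's maintenance
#' energy devoted to prophages equals the density itself.
#'
#' @param maintenance_atp_per_hr Whole-cell maintenance cost in ATP/hr
#'   (default 0.2e9).
#' @param density Genomic prophage density (prophage bp per host bp;
#'   default 0.024).
#' @param genome_bp Genome length in bp (default 5.1e6).
#' @return One-row tibble: `prophage_atp_per_hr` (ATP/hr),
#'   `atp_per_bp_per_hr` (ATP/bp/hr), `energy_fraction` (identically the
#'   density, by the proportionality assumption).
#' @export
prophage_energy_cost <- function(maintenance_atp_per_hr = 0.2e9,
                                 density = 0.024,
                                 genome_bp = 5.1e6) {
  if (!is.numeric(genome_bp) || genome_bp <= 0)
    stop("genome_bp must be strictly positive")
  if (maintenance_atp_per_hr <= 0)
    stop("maintenance_atp_per_hr must be strictly positive")
  if (density < 0) stop("density must be non-negative")
  tibble(
    maintenance_atp_per_hr = maintenance_atp_per_hr,
    density = density,
    genome_bp = genome_bp,
    prophage_atp_per_hr = maintenance_atp_per_hr * density,
    atp_per_bp_per_hr = maintenance_atp_per_hr * density / genome_bp,
    energy_fraction = density
  )
}
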