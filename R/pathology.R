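## Disease states (MCI -> AD progression, ApoE4 genotype, cholinergic
## deficit, placebo effect) and drug interventions as transformations of
## the network and the activation pipeline.

#' Pathology state
#'
#' Snapshot of the disease at a trial time point: fractions of pyramidal
#' synapses and neurons lost, the cholinergic deficit (fractional reduction
#' of released ACh), the MCI cholinergic compensation (fractional increase)
#' and the dopaminergic placebo tone.
#'
#' @param week Trial time in weeks.
#' @param synapse_loss,neuron_loss Fractions in [0, 1).
#' @param ach_deficit Fractional reduction of free ACh in [0, 1).
#' @param ach_compensation Fractional increase of free ACh (MCI only).
#' @param da_placebo Fractional increase of dopaminergic tone.
#' @return Object of class \code{adwm_pathology}.
#' @export
pathology_state <- function(week = 0, synapse_loss = 0, neuron_loss = 0,
                            ach_deficit = 0, ach_compensation = 0,
                            da_placebo = 0) {
  fr <- c(synapse_loss, neuron_loss, ach_deficit, ach_compensation, da_placebo)
  if (any(fr < 0) || any(fr[1:3] >= 1)) stop("fractions must lie in [0, 1)")
  if (week < 0) stop("`week` must be non-negative")
  structure(list(week = week, synapse_loss = synapse_loss,
                 neuron_loss = neuron_loss, ach_deficit = ach_deficit,
                 ach_compensation = ach_compensation, da_placebo = da_placebo),
            class = "adwm_pathology")
}

#' @export
print.adwm_pathology <- function(x, ...) {
  cat(sprintf(paste0("<pathology> week %g: %.1f%% synapse loss, %.1f%% neuron loss,",
                     " ACh deficit %.1f%%"),
              x$week, 100 * x$synapse_loss, 100 * x$neuron_loss,
              100 * x$ach_deficit))
  if (x$ach_compensation > 0)
    cat(sprintf(", ACh compensation +%.1f%%", 100 * x$ach_compensation))
  if (x$da_placebo > 0)
    cat(sprintf(", DA placebo +%.1f%%", 100 * x$da_placebo))
  cat("\n")
  invisible(x)
}

#' Default progression rates and stage presets
#'
#' Losses accumulate linearly: the calibrated synapse-loss slope is
#' 0.04\%/week and the neuron-loss slope 0.25\%/week, on top of a trial
#' baseline of 5\% synapse and 5\% neuron loss at week 0.  The MCI
#' (prodromal) preset is 3\% synapse / 4\% neuron loss with a 10\%
#' cholinergic compensation.
#'
#' @return List with \code{tau_s}, \code{tau_n} (fractions per week),
#'   \code{ad_baseline} and \code{mci} pathology states, and the
#'   calibration (\code{ach_deficit_calibration}) and ApoE-experiment
#'   (\code{ach_deficit_apoe}) cholinergic deficits.
#' @export
pathology_presets <- function() {
  list(tau_s = 0.0004, tau_n = 0.0025,
       ad_baseline = pathology_state(week = 0, synapse_loss = 0.05,
                                     neuron_loss = 0.05),
       mci = pathology_state(week = 0, synapse_loss = 0.03, neuron_loss = 0.04,
                             ach_compensation = 0.10),
       ach_deficit_calibration = 0.175,
       ach_deficit_apoe = 0.30,
       da_placebo = 0.075)
}

#' Advance pathology linearly in time
#'
#' \code{loss(week) = baseline + rate * week}, capped below 1, for both
#' synapse and neuron loss.
#'
#' @param week Weeks since the trial baseline, non-negative.
#' @param rates Named vector/list with \code{tau_s} and \code{tau_n}
#'   (fraction per week, non-negative).
#' @param baseline Starting \code{\link{pathology_state}}.
#' @return The progressed state (week updated).
#' @export
progress_pathology <- function(week, rates = pathology_presets()[c("tau_s", "tau_n")],
                               baseline = pathology_presets()$ad_baseline) {
  stopifnot(inherits(baseline, "adwm_pathology"))
  if (week < 0 || rates$tau_s < 0 || rates$tau_n < 0)
    stop("week and rates must be non-negative")
  st <- baseline
  st$week <- week
  st$synapse_loss <- min(1 - 1e-9, baseline$synapse_loss + rates$tau_s * week)
  st$neuron_loss <- min(1 - 1e-9, baseline$neuron_loss + rates$tau_n * week)
  st
}

#' Lesion a network according to a pathology state
#'
#' Deletes \code{round(neuron_loss * n_pyr)} pyramidal cells, split equally
#' between the stimulated and unstimulated halves (an odd count removes the
#' extra cell from the unstimulated half, preserving the attractor
#' population), then deletes the \code{synapse_loss} fraction of surviving
#' pyramidal-origin connections, excitatory-excitatory and
#' excitatory-inhibitory at the same rate, uniformly at random under the
#' seed.  A connection is the AMPA+NMDA pair between one (pre, post) cell
#' pair.  Interneurons are never deleted.
#'
#' @param net An \code{adwm_network}.
#' @param state A \code{\link{pathology_state}}.
#' @param seed Integer seed for the random deletions.
#' @return The lesioned network.
#' @export
apply_lesion <- function(net, state, seed = 1L) {
  stopifnot(inherits(net, "adwm_network"), inherits(state, "adwm_pathology"))
  nn <- net$neurons
  n_pyr <- sum(nn$type == "pyr")
  n_del <- round(state$neuron_loss * n_pyr)
  if (n_del > n_pyr) stop("infeasible neuron loss")
  set.seed(seed)
  if (n_del > 0) {
    n_stim_del <- floor(n_del / 2)
    n_unstim_del <- n_del - n_stim_del  # odd count -> extra from unstimulated
    stim_pool <- nn$id[nn$type == "pyr" & nn$stimulated & nn$alive]
    unst_pool <- nn$id[nn$type == "pyr" & !nn$stimulated & nn$alive]
    if (n_stim_del > length(stim_pool) || n_unstim_del > length(unst_pool))
      stop("infeasible neuron loss for the surviving populations")
    del <- c(if (n_stim_del > 0) sample(stim_pool, n_stim_del),
             if (n_unstim_del > 0) sample(unst_pool, n_unstim_del))
    nn$alive[nn$id %in% del] <- FALSE
  }
  net$neurons <- nn
  alive <- nn$id[nn$alive]
  syn <- net$synapses
  keep_alive <- syn$pre %in% alive & syn$post %in% alive
  syn <- syn[keep_alive, ]
  if (state$synapse_loss > 0) {
    for (cl in c("ee", "ei")) {
      rows <- which(syn$class == cl)
      pairs <- unique(syn[rows, c("pre", "post")])
      n_cut <- round(state$synapse_loss * nrow(pairs))
      if (n_cut > 0) {
        cut <- pairs[sample(nrow(pairs), n_cut), ]
        drop <- rows[paste(syn$pre[rows], syn$post[rows]) %in%
                       paste(cut$pre, cut$post)]
        syn <- syn[-drop, ]
      }
    }
  }
  rownames(syn) <- NULL
  net$synapses <- syn
  net
}

#' ApoE4 genotype adjustment
#'
#' Adds the genotype-specific synapse loss (3\% for one ApoE4 allele, 5\%
#' for two) on top of the current pathology; homozygous carriers
#' additionally lose cholinergic tone (a further fractional ACh reduction,
#' composed multiplicatively with the existing deficit).
#'
#' @param state A \code{\link{pathology_state}}.
#' @param apoe4_alleles 0, 1 or 2.
#' @param extra_ach_reduction Additional ACh reduction for homozygous
#'   carriers (fraction, default 0.10).
#' @return The adjusted state.
#' @export
apply_apoe <- function(state, apoe4_alleles, extra_ach_reduction = 0.10) {
  stopifnot(inherits(state, "adwm_pathology"))
  if (!apoe4_alleles %in% 0:2) stop("`apoe4_alleles` must be 0, 1 or 2")
  add <- c(0, 0.03, 0.05)[apoe4_alleles + 1]
  state$synapse_loss <- min(1 - 1e-9, state$synapse_loss + add)
  if (apoe4_alleles == 2)
    state$ach_deficit <- 1 - (1 - state$ach_deficit) * (1 - extra_ach_reduction)
  state
}

#' Memantine NMDA transform
#'
#' Weak uncompetitive NMDA antagonism with subunit selectivity: reduces the
#' NMDA conductance of excitatory-excitatory synapses by \code{ee_frac}
#' (NR2A/B, on pyramids) and of excitatory-inhibitory synapses by
#' \code{ei_frac} (NR2C/D, on interneurons).  Defaults are the clinical
#' memantine setting (0.5\% and 1\%); equal fractions give the hypothetical
#' subunit-nonselective compound.
#'
#' @param net An \code{adwm_network}.
#' @param ee_frac,ei_frac Fractions in [0, 1).
#' @return The transformed network (only NMDA \code{gbar_uS} changes).
#' @export
apply_memantine <- function(net, ee_frac = 0.005, ei_frac = 0.01) {
  stopifnot(inherits(net, "adwm_network"))
  if (any(c(ee_frac, ei_frac) < 0) || any(c(ee_frac, ei_frac) >= 1))
    stop("fractions must lie in [0, 1)")
  syn <- net$synapses
  ee <- syn$kind == "nmda" & syn$class == "ee"
  ei <- syn$kind == "nmda" & syn$class == "ei"
  syn$gbar_uS[ee] <- syn$gbar_uS[ee] * (1 - ee_frac)
  syn$gbar_uS[ei] <- syn$gbar_uS[ei] * (1 - ei_frac)
  net$synapses <- syn
  net
}

#' Drug intervention
#'
#' @param drug Drug name (or \code{"placebo"}).
#' @param dose_mg Dose in mg, non-negative.
#' @param mechanism One of \code{"AChE-I"}, \code{"5HT6-antagonist"},
#'   \code{"memantine"}, \code{"placebo"}; inferred from the drug name when
#'   possible.
#' @param memantine_ee,memantine_ei NMDA reduction fractions for the
#'   memantine mechanism.
#' @return Object of class \code{adwm_intervention}.
#' @export
intervention <- function(drug, dose_mg = 0, mechanism = NULL,
                         memantine_ee = 0.005, memantine_ei = 0.01) {
  known <- c(donepezil = "AChE-I", galantamine = "AChE-I",
             rivastigmine = "AChE-I", `SB-742457` = "5HT6-antagonist",
             SB742457 = "5HT6-antagonist", memantine = "memantine",
             placebo = "placebo")
  if (is.null(mechanism)) {
    if (!drug %in% names(known))
      stop("unknown drug '", drug, "'; known mechanisms: ",
           paste(unique(known), collapse = ", "))
    mechanism <- known[[drug]]
  }
  mechanism <- match.arg(mechanism,
                         c("AChE-I", "5HT6-antagonist", "memantine", "placebo"))
  if (dose_mg < 0) stop("`dose_mg` must be non-negative")
  structure(list(drug = drug, dose_mg = dose_mg, mechanism = mechanism,
                 memantine_ee = memantine_ee, memantine_ei = memantine_ei),
            class = "adwm_intervention")
}

#' Assemble a runnable trial condition
#'
#' Composes the pathology progression, the dose chain of the drug, the
#' week-12 placebo effect, genotype adjustments and any network transforms
#' into a single condition object that \code{\link{run_condition}} can
#' execute.
#'
#' @param drug An \code{\link{intervention}} (or drug name, with
#'   \code{dose_mg}).
#' @param week Trial week (the clinical table uses 12, 26, 52, 78).
#' @param dose_mg Dose when \code{drug} is given as a name.
#' @param apoe4_alleles ApoE4 allele count, default 0.
#' @param baseline Pathology baseline (default: AD trial baseline, 5\%/5\%).
#' @param ach_deficit Cholinergic deficit of the AD state (default: the
#'   calibrated 0.175; the ApoE experiments use 0.30).
#' @param presets \code{\link{pathology_presets}} bundle (rates, placebo).
#' @return Object of class \code{adwm_condition}: \code{state},
#'   \code{intervention}, \code{id}.
#' @export
build_condition <- function(drug, week, dose_mg = 0, apoe4_alleles = 0,
                            baseline = NULL, ach_deficit = NULL,
                            presets = pathology_presets()) {
  if (!inherits(drug, "adwm_intervention")) drug <- intervention(drug, dose_mg)
  if (is.null(baseline)) baseline <- presets$ad_baseline
  st <- progress_pathology(week, presets[c("tau_s", "tau_n")], baseline)
  st$ach_deficit <- if (is.null(ach_deficit)) presets$ach_deficit_calibration
    else ach_deficit
  if (week >= 12) st$da_placebo <- presets$da_placebo
  if (apoe4_alleles > 0) st <- apply_apoe(st, apoe4_alleles)
  id <- sprintf("%s_%gmg_wk%g%s", drug$drug, drug$dose_mg, week,
                if (apoe4_alleles > 0) paste0("_apoe", apoe4_alleles) else "")
  structure(list(state = st, intervention = drug, id = id,
                 apoe4_alleles = apoe4_alleles),
            class = "adwm_condition")
}

#' @export
print.adwm_condition <- function(x, ...) {
  cat(sprintf("<condition> %s (%s)\n", x$id, x$intervention$mechanism))
  print(x$state)
  invisible(x)
}
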