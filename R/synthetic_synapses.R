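#' Simulate an EM synapse measurement table
#'
#' One record per measured active zone. Each synapse is Bernoulli-perforated
#' with the group's probability; a perforated synapse contributes two active
#' zone records sharing its synapse id (its active zone is split into two
#' zones from the same terminal onto the same postsynaptic element). Active
#' zone lengths are drawn log-normal with perforation-specific parameters;
#' the postsynaptic target (spine / dendrite / unidentified) is categorical
#' with group-specific probabilities; patient ages are Normal per group.
#'
#' @param cfg a \code{\link{simConfig}} (fields \code{nPatients},
#'   \code{synapsesPerPatient}, \code{perfProb}, \code{spineProb},
#'   \code{dendriteProb}, \code{multiTargetProb}, \code{lengthMeanlog},
#'   \code{lengthSdlog}, \code{ageMean}, \code{ageSd}).
#' @param seed RNG seed; defaults to \code{cfg$seed + 4}.
#' @return data.frame in the synapse-table layout of
#'   \code{\link{readSynapseTable}}: patient_id, group, region, synapse_id,
#'   az_length_um, perforated, target, multi_target, age.
#' @export
simulateSynapseTable <- function(cfg = simConfig(), seed = cfg$seed + 4L) {
    groups <- c("non-epileptic", "epileptic")
    withSeed(seed, {
        out <- list()
        sid <- 0L
        for (g in seq_along(groups)) {
            grp <- groups[g]
            pSpine <- cfg$spineProb[[grp]]
            pDend <- cfg$dendriteProb[[grp]]
            for (p in seq_len(cfg$nPatients[g])) {
                pid <- sprintf("%s-P%d", substr(grp, 1, 3), p)
                age <- max(18, stats::rnorm(1, cfg$ageMean[[grp]],
                                            cfg$ageSd[[grp]]))
                nSyn <- cfg$synapsesPerPatient
                for (s in seq_len(nSyn)) {
                    sid <- sid + 1L
                    perf <- stats::runif(1) < cfg$perfProb[[grp]]
                    nz <- if (perf) 2L else 1L
                    key <- if (perf) "perforated" else "non-perforated"
                    target <- sample(c("spine", "dendrite", "unidentified"),
                                     1, prob = c(pSpine, pDend,
                                                 max(0, 1 - pSpine - pDend)))
                    out[[length(out) + 1L]] <- data.frame(
                        patient_id = pid, group = grp,
                        region = sample(c("SPA", "NoSPA"), 1),
                        synapse_id = sprintf("syn%05d", sid),
                        az_length_um = stats::rlnorm(nz,
                            cfg$lengthMeanlog[[key]], cfg$lengthSdlog[[key]]),
                        perforated = perf, target = target,
                        multi_target = stats::runif(1) < cfg$multiTargetProb,
                        age = age, stringsAsFactors = FALSE)
                }
            }
        }
        x <- do.call(rbind, out)
        rownames(x) <- NULL
        validateSynapseTable(x)
        x
    })
}
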