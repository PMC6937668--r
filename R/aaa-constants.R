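# Internal constants for the compartment state space. This file loads first.

.t2d_env <- new.env(parent = emptyenv())

SEXES <- c("female", "male")
N_AGE <- 16L
AGE_BANDS <- c(paste(seq(0, 70, 5), seq(4, 74, 5), sep = "-"), "75+")
AGE_MID <- c(seq(2.5, 72.5, 5), 80)
AGE_LOW <- seq(0, 75, 5)
FACTORS <- c("obesity", "smoking", "inactivity")
STATES <- c("sus_none", "sus_pa", "t2dm")
# 15-64 reporting window: bands 15-19 ... 60-64
ADULT_BANDS <- 4:13
N_STRATA <- 2L * N_AGE * 8L * 3L  # 768
N_STATE <- N_STRATA + 64L  # counts + cumulative case/death accumulators
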