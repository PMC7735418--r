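# shared fixture builders; everything is generated in code

tinySchema <- function()
  FeatureSchema(c("sex", "diab", "creat"),
                c("binary", "binary", "continuous"),
                normal_low = c(NA, NA, 59),
                normal_high = c(NA, NA, 104))

makeRaw <- function(features, treatments, outcome,
                    ids = as.character(seq_len(nrow(features))))
  new("RawCohort", sampleIds = ids, features = features,
      treatments = treatments, outcome = as.integer(outcome),
      filterReport = list())

# write a cohort as the CSV trio and return the paths
writeTrio <- function(raw, dir = tempfile()) {
  dir.create(dir)
  utils::write.csv(raw@features, file.path(dir, "f.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(raw@treatments),
                   file.path(dir, "a.csv"), row.names = FALSE)
  utils::write.csv(data.frame(outcome = raw@outcome),
                   file.path(dir, "y.csv"), row.names = FALSE)
  list(features = file.path(dir, "f.csv"),
       treatments = file.path(dir, "a.csv"),
       outcome = file.path(dir, "y.csv"))
}

# model with every weight and bias set to zero
zeroModel <- function(M, Kt, config = TrainConfig()) {
  m <- initModel(M, Kt, config)
  m@params <- lapply(m@params, function(net) {
    net$layers <- lapply(net$layers, function(ly) {
      ly$W[] <- 0; ly$b[] <- 0; ly
    })
    net
  })
  m
}

# replace one component with explicit single-layer parameters
setBlock <- function(model, block, W, b, act) {
  model@params[[block]] <- list(layers = list(list(
    W = W, b = b, act = act)))
  model
}

# a small encoded cohort drawn from the simulator
smallEncoded <- function(n = 200L, seed = 1L, treatmentWeight = 0,
                         strongK = 3L) {
  cfg <- SyntheticConfig(nSamples = n, seed = seed)
  if (treatmentWeight != 0)
    cfg <- plantEffectScenario(cfg, strongK, treatmentWeight)
  sim <- generateCohort(cfg)
  encodeFeatures(sim$cohort, sim$schema)
}

bruteForceAuc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
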