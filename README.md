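# rechat

Predicting **recurrent contact** at a 24/7 chat-counseling service from
privacy-preserving conversation text.

Chat hotlines for young people act as a first point of contact into mental
health care. Whether a help seeker will contact the service *again* after
their first counseling session is an objectively measurable marker of unmet
need — and a quantity worth predicting, because chatters at high risk of
recontact could be redirected proactively into routine care. `rechat`
implements the full analysis pipeline for this prediction task, built so
that every stage runs on strictly anonymized data (word stems in random
order, no narratives, no identifiers) and so that the whole pipeline is
testable on synthetic corpora with known ground truth.

## What the package does

1. **Sessionization & outcome labeling** — timestamped two-party message
   streams are segmented into *consultations* at every inactivity gap of
   ≥ 6 hours. A consultation *qualifies* when it has ≥ 3 counselor messages
   and ≥ 10 messages overall; the first qualifying consultation is the
   *index*. The binary outcome is whether any later consultation with at
   least one chatter message starts within 188 days (inclusive) of the
   index's end. Train/test splitting is time-based (half-open at the
   cutoff).
2. **Anonymization** — listed names/cities become `[NAME]`/`[CITY]` tokens;
   text is tokenized, stemmed (pluggable stemmer), shuffled into random
   order within each speaker, and stems present in fewer than 5 distinct
   chats are deleted.
3. **Features** — two TF-IDF bag-of-stems vectors per chat, one for the
   chatter's words and one for the counselor's, each with its own
   document-frequency bounds and Euclidean normalization, concatenated into
   a sparse design matrix. A metadata baseline uses only the two channel
   word counts plus the clock hour of first contact.
4. **Model** — an XGBoost classifier with the logistic objective. All
   eleven hyperparameters (4 df bounds, the idf switch, 6 booster
   parameters) are tuned *jointly* by sequential model-based (Bayesian)
   optimization over their discrete grids, scoring each candidate by
   repeated stratified k-fold cross-validated AUROC.
5. **Inference** — the corrected 5×2cv paired t-test compares the text
   pipeline against the metadata baseline
   (`t = d₁⁽¹⁾ / √(⅕ Σᵢ sᵢ²)`, 5 df, two-sided); a label-permutation test
   checks the one-time holdout AUROC against chance.
6. **Explainability** — exact TreeSHAP attributions per stem (local
   accuracy asserted), cross-channel stem co-occurrence tables, and
   k-means clustering of stem embeddings with silhouette-chosen k and
   per-cluster summed importance. Embeddings come from a word2vec text
   file or from the built-in PPMI + SVD trainer.
7. **Synthetic corpus generator** — a first-class, tested module that
   emits corpora with the statistical structure the analysis assumes:
   over-dispersed message counts (mean 25.4 / 17.7 per channel), total
   word counts (mean 456.4, capped at 3340), 43.1% recontact prevalence
   driven by a calibrated latent logistic model (young age ↑, female ↑,
   self-harm/suicide ↑, night ↑, work ↓, counselor redirection ↓), more
   than half of recontact delays within one week, and counselor mirroring
   of chatter topics in 2/3 of chats.

## Worked example

```r
library(rechat)

# 1. simulate a corpus of 2,000 chatters (or read real JSONL exports)
cfg  <- synth_config(n_chatters = 2000, seed = 42)
corp <- generate_corpus(cfg)

# 2. sessionize, label the 188-day outcome, and split by time
rec <- build_episodes(corp$messages, gap_hours = 6, window_days = 188)
rec <- time_split(rec, "2022-09-01")

# 3. anonymize: PII tokens, stemming, shuffling, rare-stem deletion
docs <- anonymize_corpus(collect_speaker_docs(corp$messages, rec))

# 4. train the dual-channel TF-IDF + boosted-tree pipeline
labels <- setNames(rec$label, rec$chat_id)
train  <- rec$chat_id[rec$split == "train"]
test   <- rec$chat_id[rec$split == "test"]
params <- pipeline_params(vectorizer_params(0.9, 25, 0.9, 10),
                          booster_params(), nrounds = 400)
model  <- fit_final(docs[docs$chat_id %in% train, ], labels, params, seed = 1)

# 5. one-time holdout evaluation + permutation significance
p <- predict(model, docs[docs$chat_id %in% test, ])[test]
metrics_report(labels[test], p)
#> <eval_report>
#>   AUROC 0.63 | accuracy 0.61 | balanced accuracy 0.58
#>   precision 0.55 | recall/sensitivity 0.42 | specificity 0.75
#>   confusion: TP 97 FP 78 TN 230 FN 134 (threshold 0.50)
permutation_test(labels[test], p, n_perm = 999, seed = 1)
#> <permutation_result> observed AUROC 0.629, p = 0.0010 (999 perms)

# 6. explain: SHAP attributions per stem
shap <- shap_attribution(model, docs[docs$chat_id %in% test, ])
head(names(shap$mean_abs), 8)
#> [1] "co_arzt"  "ch_noch"  "ch_ritz"  "co_mit"   "ch_immer" "ch_mocht"
#> [7] "co_wenn"  "co_situation"
```

The holdout AUROC of 0.63 is significantly above chance (permutation
p = 0.001) despite the small simulated corpus; at 4,000 chatters with a
tuned configuration the pipeline reaches ≈ 0.66–0.70 against a
word-count/daytime baseline of ≈ 0.55. Among the most influential stems
are planted signal carriers: `ch_ritz` (self-harm, chatter channel) and
`co_arzt` (redirection to a physician, counselor channel). Prefixes `ch_`
and `co_` mark the channel the stem was used in.

## Documentation

Function-level documentation lives in the roxygen comments under `R/`.
The methods vignette (`vignettes/methods.Rmd`) describes the generative
model, the calibration mathematics, the tuning and testing procedures, and
the known limitations of synthetic validation.
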