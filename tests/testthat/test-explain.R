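shap_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- separable_corpus(n = 80)
      m <- fit_final(sc$docs, sc$labels,
                     pipeline_params(vectorizer_params(1, 1, 1, 1),
                                     booster_params(eta = 0.3, max_depth = 3,
                                                    min_child_weight = 1,
                                                    gamma = 0, subsample = 1,
                                                    colsample_bytree = 1),
                                     nrounds = 25L), seed = 8)
      cache <<- list(model = m, docs = sc$docs, labels = sc$labels)
    }
    cache
  }
})

test_that("SHAP attributions satisfy local accuracy on every sample", {
  fx <- shap_model()
  rep <- shap_attribution(fx$model, fx$docs)
  recon <- rep$base_value + rowSums(rep$shap)
  expect_lt(max(abs(recon - rep$margin)), 1e-4)
  expect_equal(ncol(rep$shap), length(fx$model$feature_names))
  expect_equal(rep$n_chatter_features + rep$n_couns_features,
               ncol(rep$shap))
  expect_error(shap_attribution(list(), fx$docs), "rechat_model")
})

test_that("a single stump attributes the full leaf difference to its feature", {
  docs <- stem_corpus(list(
    a = list(chatter = c("hit", "pad"), counselor = "pad"),
    b = list(chatter = c("pad", "pad"), counselor = "pad"),
    c = list(chatter = c("hit", "pad"), counselor = "pad"),
    d = list(chatter = c("pad", "pad"), counselor = "pad")))
  labels <- setNames(c(TRUE, FALSE, TRUE, FALSE), c("a", "b", "c", "d"))
  m <- fit_final(docs, labels,
                 pipeline_params(vectorizer_params(1, 1, 1, 1),
                                 booster_params(eta = 1, max_depth = 1,
                                                min_child_weight = 1,
                                                gamma = 0, subsample = 1,
                                                colsample_bytree = 1),
                                 nrounds = 1L), seed = 1)
  rep <- shap_attribution(m, docs)
  # one tree, one informative feature: attribution = margin - base
  expect_equal(unname(rep$shap[, "ch_hit"]), rep$margin - rep$base_value,
               tolerance = 1e-6)
})

test_that("planted positive stems carry positive attributions where present", {
  fx <- shap_model()
  rep <- shap_attribution(fx$model, fx$docs)
  present <- vapply(
    fx$docs$stems[fx$docs$channel == "chatter"],
    function(s) "marker" %in% s, TRUE)
  vals <- rep$shap[present, "ch_marker"]
  expect_gt(mean(vals > 0), 0.9)
  expect_equal(names(rep$mean_abs)[1], "ch_marker")
})

test_that("co-occurrence counts match a manual tally on a toy corpus", {
  docs <- stem_corpus(list(
    k1 = list(chatter = c("gedank", "eltern"), counselor = c("suizid", "x")),
    k2 = list(chatter = c("gedank", "gedank"), counselor = c("suizid")),
    k3 = list(chatter = c("eltern"), counselor = c("y", "suizid")),
    k4 = list(chatter = c("gedank"), counselor = c("y"))))
  tab <- cooccurrence(docs, "suizid", "counselor", top_k = 10)
  expect_equal(attr(tab, "n_target_chats"), 3L)
  expect_equal(tab$n_chats[tab$stem == "gedank"], 2L)
  expect_equal(tab$n_chats[tab$stem == "eltern"], 2L)
  expect_equal(tab$share[tab$stem == "gedank"], 2 / 3)

  # cross-channel share of the target stem itself (mirroring share)
  docs2 <- stem_corpus(list(
    k1 = list(chatter = c("verletz"), counselor = c("verletz")),
    k2 = list(chatter = c("x"), counselor = c("verletz")),
    k3 = list(chatter = c("verletz"), counselor = c("verletz"))))
  tab2 <- cooccurrence(docs2, "verletz", "counselor")
  expect_equal(attr(tab2, "cross_channel_share"), 2 / 3)

  absent <- cooccurrence(docs, "nichtda", "counselor")
  expect_equal(nrow(absent), 0L)
  expect_equal(attr(absent, "n_target_chats"), 0L)
})

test_that("counselors mirror active chatter topics at the mirror rate", {
  corp <- small_corpus()
  rec <- build_episodes(corp$messages)
  docs <- anonymize_corpus(collect_speaker_docs(corp$messages, rec),
                           anon_config(min_chats = 2))
  lex <- default_lexicons()
  co <- docs[docs$channel == "counselor", ]
  co_stems <- setNames(co$stems, co$chat_id)
  tr <- corp$truth
  share <- vapply(c("self_harm", "suicide", "work"), function(topic) {
    act <- tr$chat_id[tr[[topic]]]
    mean(vapply(co_stems[act], function(s) any(lex[[topic]] %in% s), TRUE))
  }, 0)
  # ~2/3 of chats with an active chatter topic see it echoed by the
  # counselor (wider tolerance than at full corpus scale)
  expect_true(all(abs(share - 2 / 3) < 0.12))
  # cross-channel share of one specific stem stays below the topic rate:
  # the counselor may echo a different stem of the same topic
  tab <- cooccurrence(docs, "verletz", "chatter")
  expect_lt(attr(tab, "cross_channel_share"), 2 / 3 + 0.05)
  expect_gt(attr(tab, "cross_channel_share"), 0.35)
})

test_that("embedding clustering picks the obvious k and conserves importance", {
  withr::with_seed(5, {
    emb <- rbind(matrix(rnorm(20 * 4, mean = 0), 20, 4),
                 matrix(rnorm(20 * 4, mean = 8), 20, 4))
    rownames(emb) <- paste0("w", 1:40)
  })
  imp <- setNames(runif(40, 0.1, 1), paste0("w", 1:40))
  rep <- embed_cluster(paste0("w", 1:40), imp, emb, k_range = 2:6, seed = 2)
  expect_equal(rep$k, 2L)
  expect_gt(max(rep$silhouette$score), 0.8)
  expect_equal(sum(rep$importance), sum(imp))
  expect_equal(sum(rep$size), 40L)
  expect_equal(rep$n_missing, 0L)
  # stems without vectors are excluded and counted
  rep2 <- embed_cluster(c(paste0("w", 1:40), "fehlt"), c(imp, fehlt = 1),
                        emb, k_range = 2:4, seed = 2)
  expect_equal(rep2$n_missing, 1L)
  expect_equal(sum(rep2$importance), sum(imp))
  expect_error(embed_cluster(c("a", "b"), c(1, 2), emb, k_range = 5:6),
               "embeddable")
})

test_that("restart-seeded k-means reproduces an explicit Lloyd re-run", {
  withr::with_seed(9, {
    V <- matrix(rnorm(20 * 3), 20, 3)
    rownames(V) <- paste0("p", 1:20)
  })
  km <- rechat:::kmeans_restarts(V, k = 3, n_restarts = 4, seed = 13)
  oracle <- withr::with_seed(13, {
    best <- NULL
    for (j in 1:4) {
      centers <- V[sample.int(nrow(V), 3), , drop = FALSE]
      cand <- suppressWarnings(kmeans(V, centers = centers, iter.max = 100,
                                      algorithm = "Lloyd"))
      if (is.null(best) || cand$tot.withinss < best$tot.withinss)
        best <- cand
    }
    best
  })
  expect_equal(km$cluster, oracle$cluster)
  expect_equal(km$tot.withinss, oracle$tot.withinss)
})

test_that("corpus-trained embeddings place same-topic stems nearby", {
  corp <- small_corpus()
  emb <- train_embeddings(corp$messages$text, dim = 30, window = 4,
                          min_count = 5)
  lex <- default_lexicons()
  expect_true(all(lex$self_harm %in% rownames(emb)))
  # cosine similarity within the self-harm lexicon vs to background stems
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sh <- lex$self_harm
  within <- mean(utils::combn(sh, 2, function(p)
    cosine(emb[p[1], ], emb[p[2], ])))
  across <- mean(vapply(sh, function(s)
    cosine(emb[s, ], emb["hallo", ]), 0))
  expect_gt(within, across)
})

test_that("word2vec text files round-trip", {
  f <- file.path(tempdir(), "vec.txt")
  writeLines(c("3 4",
               "haus 0.1 0.2 0.3 0.4",
               "baum 1 0 0 1",
               "tuer -1 0.5 0.25 0"), f)
  v <- read_word2vec(f)
  expect_equal(dim(v), c(3L, 4L))
  expect_equal(v["tuer", ], c(-1, 0.5, 0.25, 0))
  # headerless variant
  writeLines(c("haus 1 2", "baum 3 4"), f)
  expect_equal(read_word2vec(f)["baum", ], c(3, 4))
})
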