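# dsclust

Double-target self-supervised clustering of short texts in R.

Short documents — medical question-and-answer posts, support tickets, search
queries — are hard to cluster: a handful of tokens gives sparse bag-of-words
vectors, and there are no labels to train on. `dsclust` implements a deep
clustering method for this regime that needs nothing but the raw tokenized
corpus:

1. **Fused lexical features.** Each token is embedded with subword skip-gram
   vectors (character n-grams, so unseen words still embed) and scaled by its
   TF-IDF weight, giving a document matrix `FW ∈ R^{k×d}` whose rows
   down-weight uninformative words.
2. **Sequence encoder.** A bidirectional GRU reads `FW` (states
   `H ∈ R^{k×2u}`), and a structured self-attention layer
   `A = softmax(W₂ tanh(W₁ Hᵀ))` pools the positions into a fixed-length
   text representation `M ∈ R^{r}`.
3. **Double self-supervised target.** The encoder is trained end-to-end
   against `L = α·L_cluster + L_topic`, where
   `L_topic = KL(T ‖ D) = Σᵢⱼ tᵢⱼ ln(tᵢⱼ/dᵢⱼ)` pulls the model's topic
   posterior `D = softmax(W₂ ReLU(W₁ᵀ M))` toward a frozen LDA
   document-topic distribution `T` (cross-document information), and
   `L_cluster = Σᵢ ‖xᵢ − c_{a(i)}‖²` attracts each encoded feature to its
   within-batch k-means centroid. The weight climbs linearly,
   `α(t) = (t/T′)·α_max` with `α_max = 0.3`, so the centroid loss only acts
   once the features are worth clustering.
4. **Evaluation.** Optimal-mapping accuracy (Hungarian assignment), NMI,
   ARI and two F1 variants, all invariant to cluster relabeling.

The package also ships a labelled synthetic short-text generator with a
controllable vocabulary-overlap difficulty dial, a classical TF-IDF +
k-means baseline, and a `fit / predict / evaluate / baseline / synth`
command-line front end. The LDA (collapsed Gibbs) and subword skip-gram
trainers are compiled (Rcpp) and fully seeded; the encoder and its
backpropagation are batched R linear algebra, verified against
finite-difference gradients.

## Worked example

Cluster a synthetic corpus of 3 planted topics (100 documents each) whose
tokens come from a shared vocabulary half of the time — a moderately hard
setting:

```r
library(dsclust)

corpus <- synth_corpus(K = 3, docs_per_cluster = 100, overlap = 0.5, seed = 1)
vocab  <- build_vocabulary(corpus)
tfidf  <- compute_tfidf(corpus, vocab)
emb    <- train_embeddings(corpus, dim = 16, subword_n = 2, seed = 1)
lda    <- fit_topic_model(corpus, r_topics = 3, seed = 1)
topics <- document_topic_distribution(lda, corpus)

cfg   <- dsc_config(K = 3, batch_size = 32, epochs = 8, hidden_size = 32,
                    r_rep = 64, attn_dim = 64, seed = 1)
model <- dsc_train(corpus, emb, tfidf, topics, cfg)
model
#> <dsc_model: 3-cluster double-target encoder (hidden 32, rep 64)>
#>   8 epochs, 80 steps; final L_train 1.9957 (alpha 0.263)

evaluate_clustering(corpus$label, model$labels)
#> # A tibble: 1 × 6
#>     acc   nmi   ari f1_macro f1_pairwise     n
#>   <dbl> <dbl> <dbl>    <dbl>       <dbl> <int>
#> 1 0.997 0.983 0.990    0.997       0.993   300
```

The model recovers the planted partition almost exactly: 99.7% of documents
land in the right cluster after the optimal cluster-to-class mapping, and
NMI 0.983 says the predicted and true partitions share almost all their
information. `tidy(model)` returns the per-step loss/α trace and
`autoplot(model)` plots it. The same corpus through the classical baseline,
`baseline_tfidf_kmeans(corpus, vocab, K = 3, seed = 1)`, scores identically
here; the double-target model is designed to track the baseline on easy
data and add cross-document structure where bags of words get ambiguous.

From a shell, the same pipeline is:

```sh
dsclust synth    --outdir data --k 3 --docs-per-cluster 100 --overlap 0.5
dsclust fit      --config fit.yaml
dsclust predict  --checkpoint run/checkpoint.rds --tokens data/tokens.txt --out pred.txt
dsclust evaluate --pred pred.txt --gold data/labels.txt
```

(the script lives at `system.file("scripts", "dsclust", package = "dsclust")`).

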