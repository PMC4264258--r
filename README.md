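# contextnl

Rule-based detection of **contextual properties of medical terms in
Dutch clinical text**, in the NegEx/ConText tradition.

Clinical free text constantly mentions conditions that are *not*
present ("geen koorts"), belong to the *past* ("status na
appendectomie"), are merely *possible* ("indien koorts"), or concern
*someone else* ("moeder heeft diabetes"). Any system that mines Dutch
electronic medical records for signs, symptoms or diagnoses therefore
needs, for every marked term, three contextual properties:

| property    | values                              | default    |
|-------------|-------------------------------------|------------|
| negation    | Negated / NotNegated                | NotNegated |
| temporality | Recent / Historical / Hypothetical  | Recent     |
| experiencer | Patient / Other                     | Patient    |

(Recent means at most 2 weeks old; older conditions are Historical.)

## The algorithm

For each property the rule base holds four trigger lists: **pre-triggers**
(precede the concept; scope runs rightward to the sentence end),
**post-triggers** (scope runs leftward), **termination triggers** (cut a
running scope short) and **pseudo-triggers** (lookalikes that must not
fire, e.g. "niet minder" = "no fewer"). Every marked concept starts at
the default values; triggers found in the sentence are processed left to
right, and a concept inside a trigger's resolved scope takes the
trigger's value, later triggers overwriting earlier ones.

Dutch clinical document types differ sharply in structure, so scopes are
profiled per type: GP entries cap scopes at 6 words with `,` and `;` as
terminators, specialist letters at 10 words with `:` and `;`, radiology
and discharge letters use the full sentence. On top of the trigger pass
come three refinements:

* **GP minus rule** — GPs negate by a trailing minus sign ("koorts-");
* **combined triggers** — "Nooit urineweginfecties doorgemaakt" is
  negated by the pre/post pair *nooit…doorgemaakt*, although neither
  phrase is reliable alone;
* **temporality module** — regexes over adjusted windows around the
  concept catch historical evidence such as "3 jaar geleden", with
  guards vetoing relational-operator contexts ("als <3 weken niet
  beter") and fresh events ("net … gehad").

Evaluation follows the field's convention: one-vs-rest precision /
recall / F per property value (undefined metrics reported as `-`, never
0), plus Cohen's kappa `(p_o − p_e)/(1 − p_e)` with Altman bands for
annotator agreement. A deterministic synthetic-corpus generator with
template-defined gold labels stands in for protected clinical corpora.

## Worked example

```r
library(contextnl)

docs <- data.frame(
  id = c("d1", "d2"), doc_type = c("GP", "DL"),
  text = c("Geen koorts vandaag. koorts- bij controle.",
           "Status na appendectomie. Moeder is bekend met diabetes."))
res <- annotate_documents(docs, c("koorts", "appendectomie", "diabetes"))
res$annotations[, c("doc_id", "term", "negation", "temporality", "experiencer")]
#>   doc_id          term   negation temporality experiencer
#> 1     d1        koorts    Negated      Recent     Patient
#> 2     d1        koorts    Negated      Recent     Patient
#> 3     d2 appendectomie NotNegated  Historical     Patient
#> 4     d2      diabetes NotNegated      Recent       Other
res$manifest$trigger_usage
#>   phrase_or_rule    property count
#> 1           geen    negation     1
#> 2       gp-minus    negation     1
#> 3         moeder experiencer     1
#> 4      status na  historical     1
```

The first "koorts" is negated by the pre-trigger *geen*, the second by
the GP minus rule; "appendectomie" is historical via *status na*;
"diabetes" is experienced by the patient's mother, not the patient.

Evaluation on a synthetic gold corpus:

```r
corpus <- generate_corpus(default_mixture(n = 200, seed = 42))
pred <- annotate_documents(corpus$documents, default_term_list())
rep <- evaluate_annotations(corpus$gold, pred$annotations)
subset(rep, doc_type == "ALL" & value == "Negated")
#>   doc_type property   value n_gold  tp fp fn  tn precision recall f_score
#> 1      ALL negation Negated    112 112  0  0 688      1.00   1.00    1.00
```

## Command line

```sh
Rscript inst/scripts/contextnl annotate --docs docs.jsonl --terms terms.txt \
    --out ann.jsonl --profile paper-final
Rscript inst/scripts/contextnl evaluate --gold gold.jsonl --pred ann.jsonl --out report.json
Rscript inst/scripts/contextnl kappa --a annA.jsonl --b annB.jsonl --property negation
Rscript inst/scripts/contextnl generate --out-docs docs.jsonl --out-gold gold.jsonl --seed 42
```

Documents are JSON Lines (`{"id", "doc_type": "GP|SP|RD|DL", "text"}`),
term lists one term per line, the lexicon a TSV
(`phrase property role doc_types max_scope_tokens note`); all offsets
are 0-based half-open. Exit codes: 0 success, 2 input error, 3
configuration error.

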