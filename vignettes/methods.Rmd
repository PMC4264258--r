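---
title: "Methods: contextual property detection for Dutch clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contextual property detection for Dutch clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextnl)
```

## The model

contextnl implements a trigger–scope assertion model of the
NegEx/ConText family for Dutch clinical text. The unit of analysis is a
*concept mention*: an occurrence of a term from a user-supplied term
list, found by case-insensitive exact string matching inside one
sentence. Each mention receives exactly one value per contextual
property — negation (Negated/NotNegated), temporality
(Recent/Historical/Hypothetical, where Recent means at most two weeks
old) and experiencer (Patient/Other) — starting from the defaults
NotNegated / Recent / Patient.

The rule base is a lexicon of trigger phrases, each with a property and
one of four roles. Pre-triggers open a scope rightward from the trigger
to the sentence end; post-triggers mirror leftward; termination
triggers cut a running scope of their own property; pseudo-triggers
match but never fire, existing solely to absorb lookalikes ("niet
minder" must keep "niet" from negating). Triggers are processed left to
right, and later assignments to the same property overwrite earlier
ones — the only ordering the underlying algorithm family specifies.
Scopes never cross a sentence boundary, so negations stretching over
sentence breaks are missed by design.

Key assumptions: context is expressible through local lexical evidence
inside one sentence; the term list defines what can be annotated
(spelling variants of terms or triggers are missed — no fuzzy
matching); section structure of the document is not available.

## Document-type profiles

Dutch clinical document types differ in grammaticality, so the scope
model is profiled per type:

| type | default scope | punctuation terminators | extra rules |
|------|---------------|-------------------------|-------------|
| GP (general practitioner entries) | 6 words | `,` `;` | minus rule |
| SP (specialist letters)           | 10 words | `:` `;` | — |
| RD (radiology reports)            | sentence end | — | — |
| DL (discharge letters)            | sentence end | — | — |

Scope lengths count *words*: punctuation tokens terminate or are
skipped, but never consume scope. The caps apply to pre- and
post-triggers of all properties symmetrically — the source material
scopes "different types of clinical text" without restricting by
property, and we follow that reading. Punctuation terminators are
property-agnostic structure; lexicon termination entries stop only
their own property. An entry-level `max_scope_tokens` (e.g. 2 for the
checklist answer ": nee") overrides the profile default.

Two deliberate degenerate-input rules: a mention overlapping its own
trigger occurrence is not eligible for that trigger's value (term
list/lexicon collisions must not self-negate), and with an empty
lexicon every mention keeps all defaults.

## Document-specific refinements

**GP minus rule.** GPs negate by a trailing minus sign: "koorts-" or
"koorts -". The rule fires when the character after the mention
(allowing one space) is `-` followed by whitespace, punctuation or the
sentence end; "koorts-achtig" (hyphen joining a word) does not fire.
This interacts with tokenization: "koorts-" is one token, so concept
matching additionally accepts a mention ending one character before a
token end when the remainder is exactly a trailing hyphen.

**Combined triggers.** Some negations need a pre/post pair: in "Nooit
urineweginfecties doorgemaakt" neither *nooit* (too many false
positives alone — it was deliberately removed as a standalone trigger)
nor *doorgemaakt* suffices, but together, within a span gate of 10
tokens measured from the start of the pre occurrence to the end of the
post occurrence, they assert Negated.

**Temporality module.** Runs last, over *adjusted windows* (tighter
than trigger scopes) on both sides of the mention, with declarative
case-insensitive regexes loaded from YAML. The shipped set encodes the
two-week recency bound inside the regexes themselves: "15+ dagen
geleden", "3+ weken geleden", any "maanden/jaar geleden" are
Historical; "10 dagen geleden" is not. Guards veto a match in the same
window: relational operators next to a number ("als <3 weken niet
beter" is an instruction, not history) and the freshness markers
"net"/"recent". Year mentions ("in 2010") fire only when a document
reference year is supplied and the year strictly precedes it —
otherwise silently wrong history calls would result. The module only
*upgrades* Recent to Historical; it never overwrites a
lexicon-assigned Hypothetical, since its evidence is strictly
historical. Default windows are left 5 / right 3 tokens per pattern
(the broad bare-duration pattern uses 10), configurable per pattern.

## The shipped lexicon

The original full Dutch trigger inventory is not publicly available;
behavior under a *given* lexicon, not a specific inventory, is this
package's reproducible contract. The bundled lexicon is therefore
compact, seeded from every phrase with documented behavior, and fully
user-replaceable via TSV. Two configurations:

* **paper-final** — the conservative production list. No bare "nooit"
  (combined rule only), no "bij", and no ambiguous experiencer
  abbreviations: "pa" (dad / pathology) and "oma" (grandmother / acute
  otitis media) are excluded because they are documented heavy sources
  of experiencer false positives.
* **extended** — adds error-analysis suggestions: "blanco voor", the
  short-scope post-trigger ": nee", and the hypothetical pre-trigger
  "bij".

`validate_lexicon()` enforces two hygiene rules: every pseudo entry
must contain a non-pseudo phrase of the same property as a substring,
and phrases should use only letters/digits/space/hyphen/period. The
extended list's ": nee" deliberately violates the second rule and is
reported; the diagnostic is informational, mirroring that the phrase is
a real, documented trigger.

## Text preparation

The sentence splitter is rule-based (terminal `. ! ?` followed by
whitespace and an uppercase letter or digit, with a Dutch clinical
abbreviation stop-list and an initials guard) and deliberately
conservative: downstream context never crosses sentence boundaries, so
over-splitting loses context while under-splitting merely widens it.
It is also bypassable — `sentence()` accepts pre-split text, so any
external splitter can be plugged in.

The tokenizer splits on whitespace and isolates `, ; : . - < >` as
standalone tokens, except a hyphen attached to a preceding word
("koorts-", "koorts-achtig") — required by the GP minus rule. Concept
matching demands token-boundary alignment rather than raw substring
matching: "oma" must not match inside "stoma". Overlapping candidate
mentions resolve longest-first, then leftmost. All offsets everywhere
are 0-based half-open.

## Evaluation

Per property value, one-vs-rest: the chosen value is the positive
class, all other values of that property combined are negative.
Precision tp/(tp+fp), recall tp/(tp+fn), F the harmonic mean. Any
metric with a zero denominator is UNDEFINED, propagated (an undefined
precision makes F undefined) and rendered as `-`, never as 0. Reports
are per document type plus a micro-averaged ALL block.

Cohen's kappa uses marginal-product chance agreement and returns NA
when expected agreement is 1 (both annotators constant). Agreement
bands follow the Altman classification (≤0.20 poor, ≤0.40 fair, ≤0.60
moderate, ≤0.80 good, else very good). Kappa is computed per
property-value column as supplied; the tests verify it against an
independent count-form implementation to 1e-12.

## Synthetic corpora: what a green test establishes

`generate_corpus()` realizes sentences from templates whose *semantics*
define the gold labels — gold is never produced by running the engine,
which would make round-trip testing circular. Quota sampling draws
exact class counts per document type (a 12% negated fraction of n=1000
yields exactly 120), defaulting to the class mixture observed in
annotated Dutch clinical text: GP 12/2/1/2%, SP 15/8/2/1%, RD
16/3/1/0.1%, DL 13/6/0/2% for negated/historical/hypothetical/Other;
discharge letters ship no hypothetical template, matching their
observed 0%. The filler vocabulary is disjoint from all trigger
phrases, rule phrases and terms, so fillers cannot fire rules.

The generator emulates trigger placement, scope distances, terminators,
minus forms and duration expressions. It does **not** emulate real
clinical prose: no typos, no anonymization artifacts, no ungrammatical
telegram style, no section structure, no ambiguous triggers. A perfect
round trip on engine-consistent templates therefore establishes that
the engine implements its stated rules exactly — not that it would
reach any particular performance on real text. The adversarial suite
encodes documented failure modes (missing triggers such as ": nee",
"blanco voor", "is weg"; pseudo-trigger sentences; out-of-scope and
terminator placements; guarded durations) with an `engine_consistent`
flag recording which of them the paper-final configuration is expected
to miss; ablation tests confirm that removing the pseudo list or the GP
punctuation terminators strictly degrades negation precision.

## Numerical and design choices

* Conflict resolution: last writer wins, in strict left-to-right
  trigger order; evidence is replaced together with the value.
* Pseudo masking removes any shorter non-pseudo occurrence fully inside
  the pseudo span, regardless of property. The classical convention is
  same-property masking; with the shipped lexicon the two are
  indistinguishable, and the broader rule is the safer default against
  cross-property lookalikes.
* Rule order: core triggers → GP minus rule → combined rules →
  temporality module. Specific rules refine the generic pass; the
  temporality module is an add-on that must see the post-trigger state.
* Hypothetical values come only from lexicon triggers ("indien",
  "tenzij", extended "bij"), never from the regex module.
* The scope-versus-oracle equivalence tests compare scopes on their
  word-token membership: punctuation tokens can never carry a mention,
  so their inclusion at a scope edge is behaviorally irrelevant.
* Determinism: generation is seeded (restoring the caller's RNG state),
  annotation is RNG-free; both are byte-identical across runs.

## Known limitations

Single-sentence horizon; no section awareness; exact matching misses
every spelling variant; the bundled lexicon is a seed inventory, not a
full production list — users with access to a large Dutch trigger
inventory should load it via `read_lexicon()`; hypothetical detection
is weak by construction (few reliable Dutch lexical cues, a documented
difficulty of this algorithm family); the temporality module flags
Historical only and performs no TIMEX-style normalization.
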