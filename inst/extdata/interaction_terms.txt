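# Default biointeraction-term dictionary: common interaction verb lemmas in
# base / third-person / past inflections plus the nominal form where natural.
# Lines starting with '#' and blank lines are ignored. Edit freely.
activate
activates
activated
activation
bind
binds
bound
binding
inhibit
inhibits
inhibited
inhibition
induce
induces
induced
induction
interact
interacts
interacted
interaction
phosphorylate
phosphorylates
phosphorylated
phosphorylation
regulate
regulates
regulated
regulation
stimulate
stimulates
stimulated
stimulation
suppress
suppresses
suppressed
suppression
associate
associates
associated
association
block
blocks
blocked
cleave
cleaves
cleaved
cleavage
degrade
degrades
degraded
degradation
modulate
modulates
modulated
modulation
promote
promotes
promoted
promotion
repress
represses
repressed
repression
mediate
mediates
mediated
mediation
acetylate
acetylates
acetylated
acetylation
ubiquitinate
ubiquitinates
ubiquitinated
ubiquitination
methylate
methylates
methylated
methylation
recruit
recruits
recruited
recruitment
transactivate
transactivates
transactivated
transactivation
dimerize
dimerizes
dimerized
dimerization
cooperate
cooperates
cooperated
cooperation
antagonize
antagonizes
antagonized
antagonism
upregulate
upregulates
upregulated
upregulation
downregulate
downregulates
downregulated
downregulation
stabilize
stabilizes
stabilized
stabilization
destabilize
destabilizes
destabilized
destabilization
catalyze
catalyzes
catalyzed
catalysis
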