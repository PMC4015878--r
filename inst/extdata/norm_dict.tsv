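regulate	regulates	regulated	regulating	regulation	regulations	regulatory	regulator	regulators
induce	induces	induced	inducing	induction	inducible
repress	represses	repressed	repressing	repression	repressor	repressors
express	expresses	expressed	expressing	expression	expressions
activate	activates	activated	activating	activation	activator	activators
transcribe	transcribes	transcribed	transcribing
transcription	transcriptional	transcript	transcripts
bind	binds	bound	binding
inhibit	inhibits	inhibited	inhibiting	inhibition	inhibitor	inhibitors
suppress	suppresses	suppressed	suppressing	suppression	suppressor
control	controls	controlled	controlling
mediate	mediates	mediated	mediating
modulate	modulates	modulated	modulating	modulation
promote	promotes	promoted	promoting
promoter	promoters
degrade	degrades	degraded	degrading	degradation
stimulate	stimulates	stimulated	stimulating	stimulation
silence	silences	silenced	silencing
interact	interacts	interacted	interacting	interaction	interactions
phosphorylate	phosphorylates	phosphorylated	phosphorylation
ubiquitinate	ubiquitinates	ubiquitinated	ubiquitination	ubiquitylate	ubiquitylates	ubiquitylated	ubiquitylation
methylation	methylate	methylates	methylated	dimethylation	trimethylation	monomethylation
acetylate	acetylates	acetylated	acetylation
target	targets	targeted	targeting
signal	signals	signaled	signaling	signalling
respond	responds	responded	responding
accelerate	accelerates	accelerated	accelerating	acceleration
extend	extends	extended	extending	extension
increase	increases	increased	increasing
rise	rises	rose	risen	rising
peak	peaks	peaked	peaking
enhance	enhances	enhanced	enhancing	enhancement
assist	assists	assisted	assisting
block	blocks	blocked	blocking
prevent	prevents	prevented	preventing	prevention
abolish	abolishes	abolished	abolishing
reduce	reduces	reduced	reducing	reduction
decrease	decreases	decreased	decreasing
compromise	compromises	compromised	compromising
sustain	sustains	sustained	sustaining
alleviate	alleviates	alleviated	alleviating
decline	declines	declined	declining
lower	lowers	lowered	lowering
diminish	diminishes	diminished	diminishing
limit	limits	limited	limiting
fail	fails	failed	failing	failure
lack	lacks	lacked	lacking
delay	delays	delayed	delaying
slow	slows	slowed	slowing	slowly
alter	alters	altered	altering	alteration	alterations
exert	exerts	exerted	exerting
chromatin	euchromatin	heterochromatin
remodel	remodels	remodeled	remodeling	remodelling
nucleosome	nucleosomes	nuleosome	nuleosomes
histone	histones
chromosome	chromosomes	choromosome	choromosomes
translation	translational	translate	translates	translated	translating
replication	replicate	replicates	replicated	replicating
repair	repairs	repaired	repairing
segregation	segregate	segregates	segregated	segregating
spindle	spindles
mitosis	mitotic
cycle	cycles
codon	codons
mrna	mrnas
level	levels
activity	activities
polymerase	polymerases
gene	genes
protein	proteins
plasmid	plasmids
construct	constructs	constructed	constructing
elevate	elevates	elevated	elevating
reinforce	reinforces	reinforced	reinforcing
ribosome	ribosomes	ribosomal
metabolism	metabolic
mitochondrial	mitochondria	mitochondrion
secretion	secrete	secretes	secreted	secretory
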