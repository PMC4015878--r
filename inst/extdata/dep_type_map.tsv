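specific	generic
nsubj	subj
nsubjpass	subj
csubj	subj
csubjpass	subj
dobj	obj
iobj	obj
pobj	obj
xcomp	comp
ccomp	comp
acomp	comp
pcomp	comp
amod	mod
advmod	mod
appos	mod
nn	mod
nmod	mod
num	mod
poss	mod
rcmod	mod
partmod	mod
infmod	mod
advcl	mod
mark	mod
neg	mod
prep	prep
prepc	prep
conj	conj
cc	conj
det	det
aux	aux
auxpass	aux
cop	aux
punct	punct
dep	dep
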