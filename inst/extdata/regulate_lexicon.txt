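regulate
induce
repress
express
activate
transcribe
bind
inhibit
suppress
control
mediate
modulate
promote
degrade
stimulate
silence
interact
phosphorylate
ubiquitinate
methylate
acetylate
target
signal
respond
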