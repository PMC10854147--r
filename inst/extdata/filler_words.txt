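binding
complex
assembly
response
activity
transport
membrane
nuclear
positive
negative
cellular
protein
receptor
factor
target
early
late
core
component
organization
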