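# Synthetic stand-in for a core-essential reference list (replace with a
# published set such as the ~1580-gene core essentials for real screens).
# One symbol per line; these symbols match the simulator's gene namespace.
G000001
G000002
G000003
G000004
G000005
G000006
G000007
G000008
G000009
G000010
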