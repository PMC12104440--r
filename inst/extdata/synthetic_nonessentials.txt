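# Synthetic stand-in for a nonessential reference list.
# One symbol per line; '#' comments and blank lines are ignored.
G000011
G000012
G000013
G000014
G000015
G000016
G000017
G000018
G000019
G000020
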