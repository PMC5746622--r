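code,label
1,head
2,neck
3,chest
4,abdomen
5,pelvis
6a,proximal left upper extremity
6b,mid left upper extremity
6c,distal left upper extremity
7a,proximal right upper extremity
7b,mid right upper extremity
7c,distal right upper extremity
8a,proximal left lower extremity
8b,mid left lower extremity
8c,distal left lower extremity
9a,proximal right lower extremity
9b,mid right lower extremity
9c,distal right lower extremity
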