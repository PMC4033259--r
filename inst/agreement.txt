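Data usage agreement
--------------------
The data you are about to upload will be de-identified on this machine and
then placed in a shared archive. By continuing you confirm that:
  1. you have the right to share this data,
  2. the subjects' consent covers public sharing of de-identified images,
  3. you accept that the archive makes the data and its quality-assessment
     reports publicly available until you change the project's sharing
     policy or remove the data.
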