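# Russian function words: prepositions and the conjunction "и".
# One lowercase token per line; lines starting with '#' are comments.
# v1 — user-overridable via functionWords(path = ...).
и
в
во
на
за
к
ко
с
со
у
о
об
обо
от
ото
по
под
подо
при
про
для
до
из
изо
без
безо
над
надо
перед
передо
через
между
ради
вокруг
около
среди
против
сквозь
вдоль
возле
кроме
мимо
после
согласно
благодаря
вместо
внутри
вне
из-за
из-под
поверх
позади
помимо
насчёт
насчет
вблизи
вглубь
ввиду
вследствие
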