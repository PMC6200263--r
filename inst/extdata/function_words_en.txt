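# English function words: articles, prepositions, auxiliary verbs and "and".
# One lowercase token per line; lines starting with '#' are comments.
# v1 — user-overridable via functionWords(path = ...).
a
an
the
and
aboard
about
above
across
after
against
along
amid
among
around
at
before
behind
below
beneath
beside
besides
between
beyond
by
concerning
despite
down
during
except
for
from
in
inside
into
like
near
of
off
on
onto
out
outside
over
past
per
regarding
since
through
throughout
till
to
toward
towards
under
underneath
until
unto
up
upon
via
with
within
without
am
is
are
was
were
be
been
being
have
has
had
having
do
does
did
doing
will
would
shall
should
can
could
may
might
must
ought
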